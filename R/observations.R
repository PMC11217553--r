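#' Convert chlorophyll to phytoplankton carbon
#'
#' Uses a fixed chlorophyll-to-carbon mass ratio of 40 (1 g chlorophyll =
#' 40 g phytoplankton carbon): `mg chl m-3` becomes `mg C m-3 = ug C L-1`,
#' divided by 12.011 g mol-1 to give `umol C L-1`.
#'
#' @param chl chlorophyll concentration (mg m-3), `>= 0`.
#' @return phytoplankton carbon (umol C L-1).
#' @export
chl_to_carbon <- function(chl) {
  if (any(chl < 0, na.rm = TRUE)) stop("chlorophyll must be >= 0")
  chl * 40 / 12.011
}

#' Convert cell counts to carbon
#'
#' @param count cell concentration (cells L-1), `>= 0`.
#' @param mol_c_per_cell carbon content per cell (mol C cell-1); the default
#'   1.4e-14 is a Synechococcus-type quota.
#' @return carbon concentration (umol C L-1).
#' @export
cells_to_carbon <- function(count, mol_c_per_cell = 1.4e-14) {
  if (any(count < 0, na.rm = TRUE)) stop("cell counts must be >= 0")
  count * mol_c_per_cell * 1e6
}

#' Keep the n most abundant ASVs
#'
#' Abundance is the total read count summed over all dates. Ties at the
#' cutoff are broken by ascending ASV id, so the operation is deterministic
#' and idempotent.
#'
#' @param asv_table numeric matrix, rows = ASVs (rownames = ids),
#'   columns = dates.
#' @param n number of ASVs to retain.
#' @return the filtered matrix (identity if the table has `<= n` rows).
#' @export
prefilter_top_n <- function(asv_table, n = 10000) {
  stopifnot(n >= 1)
  if (nrow(asv_table) <= n) return(asv_table)
  totals <- rowSums(asv_table, na.rm = TRUE)
  ord <- order(-totals, rownames(asv_table))
  asv_table[sort(ord[seq_len(n)]), , drop = FALSE]
}

#' Lump phototrophic 18S ASVs into OTUs
#'
#' Drops heterotrophic and unassigned ASVs and sums the reads of ASVs
#' sharing a lumping key (by default the finest assigned taxonomic name,
#' i.e. the last field of the lineage string) into one OTU per key.
#'
#' @param asv_table read-count matrix (rows = ASVs, columns = dates).
#' @param taxonomy data frame with columns `asv_id`, `lineage`
#'   (semicolon-separated), `trophy` (one of `"phototrophic"`,
#'   `"heterotrophic"`, `"unassigned"`). ASVs without a taxonomy record are
#'   treated as unassigned (with a message).
#' @param key optional named character vector overriding the lumping key per
#'   ASV id.
#' @return OTU read-count matrix (rows = OTUs).
#' @export
classify_and_lump_18s <- function(asv_table, taxonomy, key = NULL) {
  ids <- rownames(asv_table)
  tax <- taxonomy[match(ids, taxonomy$asv_id), ]
  missing <- is.na(tax$asv_id)
  if (any(missing))
    message(sum(missing), " ASV(s) lack a taxonomy record; ",
            "treated as unassigned")
  trophy <- ifelse(missing, "unassigned", tax$trophy)
  keep <- trophy == "phototrophic"
  if (!any(keep)) {
    warning("no phototrophic ASVs retained; OTU table is empty")
    return(asv_table[integer(0), , drop = FALSE])
  }
  finest <- vapply(strsplit(tax$lineage, ";", fixed = TRUE), function(x) {
    x <- trimws(x[nzchar(trimws(x))])
    if (length(x)) x[length(x)] else NA_character_
  }, "")
  lump <- if (is.null(key)) finest else
    ifelse(ids %in% names(key), key[ids], finest)
  tab <- asv_table[keep, , drop = FALSE]
  out <- rowsum(tab, group = lump[keep])
  out[order(rownames(out)), , drop = FALSE]
}

#' Filter a 16S ASV table to heterotrophic prokaryotes
#'
#' Removes ASVs whose lineage matches chloroplasts, unassigned taxa,
#' cyanobacteria or ammonia-oxidizing archaea (configurable regular
#' expressions, matched case-insensitively).
#'
#' @param asv_table read-count matrix (rows = ASVs, columns = dates).
#' @param taxonomy data frame with `asv_id` and `lineage`.
#' @param exclude_patterns character vector of regexes for lineages to drop.
#' @return the filtered matrix (empty with a warning if all are excluded).
#' @export
filter_16s <- function(asv_table, taxonomy,
                       exclude_patterns = c("chloroplast", "unassigned",
                                            "cyanobacteria",
                                            "nitrosopumil|ammonia.?oxidi|thaumarchaeota")) {
  ids <- rownames(asv_table)
  lin <- taxonomy$lineage[match(ids, taxonomy$asv_id)]
  lin[is.na(lin)] <- "unassigned"
  drop <- Reduce(`|`, lapply(exclude_patterns, function(p)
    grepl(p, lin, ignore.case = TRUE)))
  out <- asv_table[!drop, , drop = FALSE]
  if (nrow(out) == 0)
    warning("all 16S ASVs excluded; heterotroph table is empty")
  out
}

#' Distribute pool carbon over taxa by read fraction
#'
#' Per-taxon carbon is the read fraction times the pool carbon, so taxon
#' carbon sums to the pool when fractions sum to one.
#'
#' @param read_fractions matrix (rows = taxa, columns = dates) of fractions
#'   in `[0, 1]`; per date the column sum must not exceed 1 beyond 1e-9.
#' @param pool_carbon numeric vector of pool carbon per date (umol C L-1).
#' @return matrix of per-taxon carbon (umol C L-1).
#' @export
reads_to_carbon <- function(read_fractions, pool_carbon) {
  if (any(read_fractions < 0, na.rm = TRUE))
    stop("read fractions must be >= 0")
  cs <- colSums(read_fractions, na.rm = TRUE)
  if (any(cs > 1 + 1e-9))
    stop("read fractions sum to more than 1 on ",
         sum(cs > 1 + 1e-9), " date(s)")
  sweep(read_fractions, 2, pool_carbon, `*`)
}

#' Derive nutrient loadings from a measured series
#'
#' Intrusions of different water masses appear as increases of a measured
#' nutrient total that the model cannot produce internally; they are
#' balanced by non-negative loadings. For each observation interval the
#' loading is `max(0, increase)`, reported both as a per-interval mass and
#' as a rate distributed uniformly over the interval.
#'
#' @param dates vector of dates (or numeric times in days).
#' @param values measured concentrations (umol L-1).
#' @return data frame with `start`, `end`, `loading` (umol L-1 per
#'   interval) and `rate` (umol L-1 d-1); zero rows for a single date.
#' @export
derive_nutrient_loadings <- function(dates, values) {
  keep <- !is.na(values)
  dates <- dates[keep]; values <- values[keep]
  if (length(dates) < 2)
    return(data.frame(start = dates[0], end = dates[0], loading = numeric(0),
                      rate = numeric(0)))
  o <- order(dates)
  dates <- dates[o]; values <- values[o]
  inc <- pmax(0, diff(values))
  dt <- as.numeric(diff(dates))
  data.frame(start = dates[-length(dates)], end = dates[-1], loading = inc,
             rate = inc / dt)
}

obs_series_names <- c("chlorophyll", "syn_counts", "het_counts",
                      "temperature", "par", "daylength", "poc")
obs_nutrient_names <- c("no3no2", "nh4", "po4", "si")

#' Default observation file schema
#'
#' Maps logical series to file names and column names as written by
#' [write_observation_csvs()]. ASV tables may be `"wide"` (rows = ASV ids,
#' columns = dates) or `"long"` (`asv_id`, `date`, `count`).
#'
#' @return a schema list accepted by [read_observations()].
#' @export
default_schema <- function() {
  list(asv_format = "wide",
       files = list(chlorophyll = "chlorophyll.csv",
                    nutrients = "nutrients.csv", physics = "physics.csv",
                    syn = "syn_counts.csv", het = "het_counts.csv",
                    asv18s = "asv18s.csv", tax18s = "tax18s.tsv",
                    asv16s = "asv16s.csv", tax16s = "tax16s.tsv",
                    poc = NULL),
       columns = list(date = "date", chlorophyll = "chl_mg_m3",
                      syn = "cells_per_l", het = "cells_per_l",
                      no3no2 = "no3no2", nh4 = "nh4", po4 = "po4", si = "si",
                      temp = "temp_c", par = "par", daylength = "daylength_h",
                      poc = "poc_umol_l"))
}

read_date_col <- function(df, col, file) {
  d <- as.Date(as.character(df[[col]]), format = "%Y-%m-%d")
  if (anyNA(d))
    stop("unparseable (non ISO-8601) dates in ", file)
  d
}

#' Read observation tables from disk
#'
#' Reads the weekly observation CSV/TSV set (chlorophyll, nutrients,
#' physics, cell counts, 18S/16S ASV tables and taxonomies) and aligns all
#' series on the union of dates. Dates present in one file but not another
#' yield missing values (never zeros).
#'
#' @param dir directory containing the files.
#' @param schema schema list as from [default_schema()].
#' @return an object of class `observation_set`: `dates`, per-series
#'   numeric vectors (NA = missing), `nutrients` (list per analyte),
#'   read-count matrices `asv18s`/`asv16s` with `tax18s`/`tax16s` data
#'   frames.
#' @export
read_observations <- function(dir, schema = default_schema()) {
  f <- function(name) {
    fn <- schema$files[[name]]
    if (is.null(fn)) return(NULL)
    path <- file.path(dir, fn)
    if (!file.exists(path)) stop("missing observation file: ", path)
    sep <- if (grepl("\\.tsv$", fn)) "\t" else ","
    read.csv(path, sep = sep, check.names = FALSE,
             stringsAsFactors = FALSE)
  }
  cl <- schema$columns
  chl <- f("chlorophyll"); nut <- f("nutrients"); phys <- f("physics")
  syn <- f("syn"); het <- f("het"); poc <- f("poc")
  chl$..date <- read_date_col(chl, cl$date, "chlorophyll")
  nut$..date <- read_date_col(nut, cl$date, "nutrients")
  phys$..date <- read_date_col(phys, cl$date, "physics")
  syn$..date <- read_date_col(syn, cl$date, "syn")
  het$..date <- read_date_col(het, cl$date, "het")
  if (!is.null(poc)) poc$..date <- read_date_col(poc, cl$date, "poc")

  read_asv <- function(name) {
    df <- f(name)
    if (schema$asv_format == "long") {
      df$date <- as.character(df$date)
      wide <- tapply(df$count, list(df$asv_id, df$date), sum, default = NA)
      m <- as.matrix(wide)
    } else {
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- df[[1]]
    }
    storage.mode(m) <- "double"
    if (any(m < 0, na.rm = TRUE)) stop(name, ": negative read counts")
    if (any(abs(m - round(m)) > 1e-6, na.rm = TRUE))
      stop(name, ": read counts must be integers")
    colnames(m) <- as.character(as.Date(colnames(m)))
    m
  }
  asv18s <- read_asv("asv18s"); asv16s <- read_asv("asv16s")
  tax18s <- f("tax18s"); tax16s <- f("tax16s")

  dates <- sort(unique(c(chl$..date, nut$..date, phys$..date, syn$..date,
                         het$..date, as.Date(colnames(asv18s)),
                         as.Date(colnames(asv16s)),
                         if (!is.null(poc)) poc$..date)))
  pick <- function(df, col) {
    v <- df[[col]][match(dates, df$..date)]
    as.numeric(v)
  }
  align_asv <- function(m) {
    out <- matrix(NA_real_, nrow(m), length(dates),
                  dimnames = list(rownames(m), as.character(dates)))
    hit <- match(as.Date(colnames(m)), dates)
    out[, hit] <- m
    out
  }
  obs <- list(dates = dates,
              chlorophyll = pick(chl, cl$chlorophyll),
              syn_counts = pick(syn, cl$syn),
              het_counts = pick(het, cl$het),
              nutrients = list(no3no2 = pick(nut, cl$no3no2),
                               nh4 = pick(nut, cl$nh4),
                               po4 = pick(nut, cl$po4),
                               si = pick(nut, cl$si)),
              temperature = pick(phys, cl$temp),
              par = pick(phys, cl$par),
              daylength = pick(phys, cl$daylength),
              poc = if (!is.null(poc)) pick(poc, cl$poc) else NULL,
              asv18s = align_asv(asv18s), asv16s = align_asv(asv16s),
              tax18s = tax18s, tax16s = tax16s)
  class(obs) <- "observation_set"
  validate_observations(obs)
  obs
}

#' Validate an observation set
#'
#' @param obs an `observation_set`.
#' @return `obs` invisibly; stops on negative concentrations/counts or
#'   daylength outside `[0, 24]`.
#' @export
validate_observations <- function(obs) {
  neg <- function(x) any(x < 0, na.rm = TRUE)
  if (neg(obs$chlorophyll)) stop("negative chlorophyll value")
  if (neg(obs$syn_counts) || neg(obs$het_counts))
    stop("negative cell counts")
  if (any(vapply(obs$nutrients, neg, TRUE)))
    stop("negative nutrient concentration")
  if (any(obs$daylength < 0 | obs$daylength > 24, na.rm = TRUE))
    stop("daylength must lie in [0, 24] h")
  if (neg(obs$asv18s) || neg(obs$asv16s)) stop("negative read counts")
  invisible(obs)
}

#' Convert an observation set to carbon units
#'
#' Applies the full ingest chain: 18S ASVs are prefiltered to the most
#' abundant `n_top`, classified and lumped into phototrophic OTUs, and OTU
#' read fractions are multiplied by chlorophyll-derived total phytoplankton
#' carbon. Synechococcus carbon comes from flow-cytometric counts. 16S ASVs
#' are prefiltered and cleaned of chloroplast/unassigned/cyanobacterial/
#' ammonia-oxidizer lineages; ASV read fractions are multiplied by total
#' heterotroph carbon (cell counts times a per-cell quota).
#'
#' @param obs an `observation_set`.
#' @param n_top prefilter size for both ASV tables.
#' @param het_cell_quota heterotroph carbon content (mol C cell-1).
#' @param syn_cell_quota Synechococcus carbon content (mol C cell-1).
#' @param lump_key optional per-ASV lumping key override (see
#'   [classify_and_lump_18s()]).
#' @return an object of class `carbon_observations`: `dates`,
#'   `phyto_otu_c` and `het_asv_c` matrices (taxa x dates, umol C L-1),
#'   `total_phyto_c`, `syn_c`, `total_het_c`, plus nutrients and forcing
#'   carried through.
#' @export
carbonize_observations <- function(obs, n_top = 10000,
                                   het_cell_quota = 2.0e-15,
                                   syn_cell_quota = 1.4e-14,
                                   lump_key = NULL) {
  euk_c <- chl_to_carbon(obs$chlorophyll)
  t18 <- prefilter_top_n(obs$asv18s, n_top)
  otu <- classify_and_lump_18s(t18, obs$tax18s, key = lump_key)
  frac18 <- fraction_table(otu)
  phyto_otu_c <- reads_to_carbon(frac18, euk_c)

  syn_c <- cells_to_carbon(obs$syn_counts, syn_cell_quota)
  total_het_c <- cells_to_carbon(obs$het_counts, het_cell_quota)

  t16 <- prefilter_top_n(obs$asv16s, n_top)
  hets <- filter_16s(t16, obs$tax16s)
  frac16 <- fraction_table(hets)
  het_asv_c <- reads_to_carbon(frac16, total_het_c)

  out <- list(dates = obs$dates, total_phyto_c = euk_c + ifelse(is.na(syn_c), 0, syn_c),
              euk_phyto_c = euk_c, phyto_otu_c = phyto_otu_c, syn_c = syn_c,
              het_asv_c = het_asv_c, total_het_c = total_het_c,
              nutrients = obs$nutrients, temperature = obs$temperature,
              par = obs$par, daylength = obs$daylength)
  class(out) <- "carbon_observations"
  out
}

# Read fractions per date (columns renormalized over the retained taxa).
fraction_table <- function(tab) {
  tot <- colSums(tab)
  frac <- sweep(tab, 2, tot, `/`)
  frac[, !is.na(tot) & tot == 0] <- 0
  frac
}

#' Write carbon observations as a tidy CSV
#'
#' @param cobs a `carbon_observations`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_carbon_csv <- function(cobs, path) {
  long <- function(m, ids = rownames(m)) {
    data.frame(taxon_id = rep(ids, each = length(cobs$dates)),
               date = rep(cobs$dates, length(ids)),
               carbon_umol_per_l = as.vector(t(m)))
  }
  df <- rbind(long(cobs$phyto_otu_c),
              long(matrix(cobs$syn_c, 1), "synechococcus"),
              long(cobs$het_asv_c),
              long(matrix(cobs$total_phyto_c, 1), "total_phytoplankton"),
              long(matrix(cobs$total_het_c, 1), "total_heterotrophs"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
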