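# Reading, validating, filtering and aggregating raw fishing-set records.
#
# The analysis unit is the fishing cruise: longline sets within a cruise are
# not independent samples, so catches and effort are summed and environmental
# covariates averaged over the member sets before any modeling.

SITES <- c("BV", "PA", "CS")
GEARS <- c("longline", "drumline")

#' Environmental covariate names of a set/cruise table
#' @return character vector of the nine environmental covariate columns
#'   (temp, salin, visib, tidamp, pluvio, winddir, windspe, solarrad, lunday).
#' @export
env_covariates <- function() env_covariate_names()

default_schema <- function() {
  nm <- c("cruise_id", "date", "site", "gear", "hooks")
  stats::setNames(as.list(nm), nm)
}

#' Read a delimited fishing-set table
#'
#' Reads a delimited text file (comma default, tab accepted) with a header
#' row into one record per fishing set. Species-count columns are declared in
#' the schema; blank environmental cells become `NA` (never zero).
#'
#' @param path file path.
#' @param schema named list mapping canonical fields (`cruise_id`, `date`,
#'   `site`, `gear`, `hooks`) to the file's column names, plus `species`
#'   (character vector of count columns) and optionally `env` (environmental
#'   columns; defaults to those of [env_covariates()] present in the file).
#' @param sep field separator (`","` or `"\t"`).
#' @return data.frame of set records with canonical column names; species
#'   counts are normalized to lowercase keys.
#' @export
read_set_table <- function(path, schema = list(), sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sch <- utils::modifyList(default_schema(), schema)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA"))
  required <- unlist(sch[c("cruise_id", "date", "site", "gear", "hooks")])
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    stop(sprintf("schema error: required column(s) missing: %s",
                 paste(miss, collapse = ", ")))
  }
  species <- if (is.null(sch$species)) character(0) else sch$species
  miss_sp <- setdiff(species, names(raw))
  if (length(miss_sp)) {
    stop(sprintf("schema error: species column(s) missing: %s",
                 paste(miss_sp, collapse = ", ")))
  }
  envc <- if (is.null(sch$env)) intersect(env_covariate_names(), names(raw))
          else sch$env
  parse_num <- function(col, what) {
    x <- raw[[col]]
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad)) {
      stop(sprintf("parse error: non-numeric %s '%s' in row %d of %s",
                   what, x[bad[1]], bad[1], path))
    }
    v
  }
  out <- data.frame(
    cruise_id = as.character(raw[[sch$cruise_id]]),
    date = as.Date(raw[[sch$date]]),
    site = as.character(raw[[sch$site]]),
    gear = tolower(as.character(raw[[sch$gear]])),
    hooks = parse_num(sch$hooks, "hooks"),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$date)) {
    stop(sprintf("parse error: unreadable date in row %d",
                 which(is.na(out$date))[1]))
  }
  bad_site <- setdiff(unique(out$site), SITES)
  if (length(bad_site)) {
    stop(sprintf("unknown site code(s): %s", paste(bad_site, collapse = ", ")))
  }
  bad_gear <- setdiff(unique(out$gear), GEARS)
  if (length(bad_gear)) {
    stop(sprintf("unknown gear(s): %s", paste(bad_gear, collapse = ", ")))
  }
  if (any(is.na(out$hooks) | out$hooks <= 0)) {
    stop(sprintf("invalid hooks value in row %d",
                 which(is.na(out$hooks) | out$hooks <= 0)[1]))
  }
  for (spc in species) {
    key <- normalize_species(spc)
    v <- parse_num(spc, sprintf("catch (%s)", spc))
    v[is.na(v)] <- 0
    if (any(v < 0 | v != round(v))) {
      stop(sprintf("parse error: invalid catch count in column '%s' row %d",
                   spc, which(v < 0 | v != round(v))[1]))
    }
    out[[key]] <- as.integer(v)
  }
  for (ec in envc) {
    v <- parse_num(ec, sprintf("covariate (%s)", ec))
    if (ec == "winddir" && any(!is.na(v) & (v < 0 | v >= 360))) {
      stop("winddir values must lie in [0, 360)")
    }
    if (ec == "lunday" && any(!is.na(v) & (v < 1 | v > 30))) {
      stop("lunday values must lie in [1, 30]")
    }
    out[[ec]] <- v
  }
  attr(out, "species") <- vapply(species, normalize_species, "")
  attr(out, "env") <- envc
  out
}

# Lowercase binomial keys; single-word/unknown names pass through lowercased.
normalize_species <- function(x) {
  gsub("[ .]+", "_", tolower(trimws(x)))
}

#' Standardization filters for abundance analyses
#'
#' Retains only longline sets (drumline gear had different effort and spatial
#' arrangement) dated after the gear standardization: the window from May
#' 2004 through August 2005 inclusive is discarded, so only sets on/after
#' 2005-09-01 survive. Order is preserved; an empty result is permitted.
#'
#' @param sets set-record data.frame from [read_set_table()].
#' @return filtered data.frame.
#' @export
apply_standardization_filters <- function(sets) {
  keep <- sets$gear == "longline" & sets$date >= as.Date("2005-09-01")
  out <- sets[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("species", "env")) attr(out, a) <- attr(sets, a)
  out
}

#' Aggregate fishing sets into cruise-level samples
#'
#' One row per (cruise_id, site): hooks and species counts are summed and
#' each environmental covariate is averaged over its non-missing member
#' values (missing only if all members are missing). The cruise date is the
#' earliest member date; `month` is its calendar month treated as a
#' continuous 1-12 covariate, `year` the decimal year, and
#' `quarter = ceiling(month / 3)`. Sets of one cruise spanning more than 7
#' days raise a validation error (a mis-keyed cruise id).
#'
#' @param sets filtered set-record data.frame.
#' @param species optional species column names; defaults to the `species`
#'   attribute left by [read_set_table()].
#' @return cruise-level data.frame with columns `cruise_id`, `site`, `date`,
#'   `year`, `month`, `quarter`, `effort_hooks`, species counts and averaged
#'   covariates.
#' @export
aggregate_by_cruise <- function(sets, species = attr(sets, "species")) {
  if (is.null(species)) {
    species <- setdiff(names(sets),
                       c("cruise_id", "date", "site", "gear", "hooks",
                         env_covariate_names()))
  }
  envc <- intersect(if (is.null(attr(sets, "env"))) env_covariate_names()
                    else attr(sets, "env"), names(sets))
  if (nrow(sets) == 0) {
    out <- data.frame(cruise_id = character(), site = character(),
                      date = as.Date(character()), year = numeric(),
                      month = numeric(), quarter = integer(),
                      effort_hooks = integer())
    for (s in species) out[[s]] <- integer()
    for (e in envc) out[[e]] <- numeric()
    return(out)
  }
  key <- interaction(sets$cruise_id, sets$site, drop = TRUE, sep = "\r")
  idx <- split(seq_len(nrow(sets)), key)
  # preserve first-appearance order of cruises
  idx <- idx[order(vapply(idx, min, 1L))]
  rows <- lapply(idx, function(i) {
    g <- sets[i, , drop = FALSE]
    span <- as.numeric(max(g$date) - min(g$date))
    if (span > 7) {
      stop(sprintf("validation error: sets of cruise '%s' span %d days (> 7); likely mis-keyed cruise_id",
                   g$cruise_id[1], as.integer(span)))
    }
    d0 <- min(g$date)
    lt <- as.POSIXlt(d0)
    mon <- lt$mon + 1
    row <- data.frame(cruise_id = g$cruise_id[1], site = g$site[1], date = d0,
                      year = 1900 + lt$year + lt$yday / 365,
                      month = as.numeric(mon),
                      quarter = as.integer(ceiling(mon / 3)),
                      effort_hooks = as.integer(sum(g$hooks)),
                      stringsAsFactors = FALSE)
    for (s in species) row[[s]] <- as.integer(sum(g[[s]]))
    for (e in envc) {
      v <- g[[e]]
      row[[e]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "species") <- species
  out
}

#' Write a cruise (or set) table as delimited text
#'
#' @param x data.frame.
#' @param path output path.
#' @param sep separator (same dialect as the reader: `","` or `"\t"`).
#' @export
write_cruise_table <- function(x, path, sep = ",") {
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
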