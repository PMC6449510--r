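# Data model and tabular I/O for the global CUE observation table.
# A dataset is a plain data.frame, one row per literature measurement, with
# the standard columns below; `provenance` metadata rides along as an
# attribute so ordinary data.frame manipulation still works.

#' Standard column names of a CUE observation table
#'
#' Column order and types of the canonical observation schema. Every I/O and
#' analysis function in the package addresses columns by these names; a
#' `dialect` mapping on read translates foreign headers into them.
#'
#' @return Named character vector: standard column name -> storage type
#'   (`"character"` or `"numeric"`).
#' @export
cue_schema <- function() {
  c(record_id = "character", site_id = "character",
    latitude = "numeric", longitude = "numeric",
    mat = "numeric", map = "numeric", ph = "numeric", cn_ratio = "numeric",
    pft = "character", incubation_temp = "numeric",
    substrate_text = "character", substrate_category = "character",
    cue = "numeric", delta_mbc = "numeric", delta_c_substrate = "numeric",
    r_cumulative = "numeric", resp_rate = "numeric", duration = "numeric",
    source_year = "numeric")
}

.pft_levels <- c("forest", "shrubland", "grassland", "cropland", "tundra", "other")

# columns that can satisfy the "raw quantities" requirement
.raw_columns <- c("delta_mbc", "delta_c_substrate", "r_cumulative",
                  "resp_rate", "duration")

#' Read a CUE observation table from delimited text
#'
#' Reads a comma-separated, UTF-8, header-row file into the standard
#' observation schema. Unknown extra columns are ignored. Empty cells and the
#' strings `"NA"`/`"NaN"` are treated as missing. Numeric fields that fail to
#' parse become missing; the affected cells are recorded in the
#' `read_issues` attribute rather than aborting the read (content-level
#' violations are the job of [validate_cue_dataset()]).
#'
#' @param path Path to a CSV file.
#' @param dialect Optional named character vector mapping standard column
#'   names (see [cue_schema()]) to the names used in the file, e.g.
#'   `c(cue = "CUE", incubation_temp = "Temp_C")`. Unmapped columns are
#'   looked up under their standard names.
#' @return A data.frame in the standard schema with attributes `provenance`
#'   (list: `source`, `n_rows`) and `read_issues` (data.frame of coerced
#'   cells, possibly empty).
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_cue_dataset(generate_cue_dataset(generator_config(n = 5, seed = 1)), f)
#' ds <- read_cue_dataset(f)
#' nrow(ds)
read_cue_dataset <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = c("", "NA", "NaN"), fileEncoding = "UTF-8")
  schema <- cue_schema()
  file_name <- function(std) {
    if (!is.null(dialect) && std %in% names(dialect)) dialect[[std]] else std
  }
  present <- vapply(names(schema), function(std) file_name(std) %in% names(raw),
                    logical(1))
  # mandatory: a record identifier, and either cue or at least one raw column
  missing_mandatory <- character(0)
  if (!present[["record_id"]]) missing_mandatory <- c(missing_mandatory, file_name("record_id"))
  if (!present[["cue"]] && !any(present[.raw_columns]))
    missing_mandatory <- c(missing_mandatory,
                           paste0(file_name("cue"), " (or raw-quantity columns ",
                                  paste(vapply(.raw_columns, file_name, ""), collapse = "/"), ")"))
  if (length(missing_mandatory) > 0)
    stop("header lacks mandatory column(s): ", paste(missing_mandatory, collapse = "; "))

  issues <- list()
  out <- lapply(names(schema), function(std) {
    if (!present[[std]]) {
      return(if (schema[[std]] == "numeric") rep(NA_real_, nrow(raw))
             else rep(NA_character_, nrow(raw)))
    }
    col <- raw[[file_name(std)]]
    if (schema[[std]] == "numeric") {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad) > 0)
        issues[[std]] <<- data.frame(row = bad, field = std,
                                     value = col[bad], stringsAsFactors = FALSE)
      num
    } else col
  })
  names(out) <- names(schema)
  ds <- as.data.frame(out, stringsAsFactors = FALSE)
  attr(ds, "provenance") <- list(source = path, n_rows = nrow(ds))
  attr(ds, "read_issues") <- if (length(issues) > 0) do.call(rbind, issues)
  else data.frame(row = integer(0), field = character(0), value = character(0))
  ds
}

#' Write a CUE observation table to CSV
#'
#' Numeric columns are written with 17 significant digits so a
#' write-then-read round trip reproduces every value to full double
#' precision.
#'
#' @param ds Observation data.frame (standard schema or any data.frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cue_dataset <- function(ds, path) {
  out <- as.data.frame(lapply(ds, function(col) {
    if (is.numeric(col)) {
      s <- vapply(col, function(x) if (is.na(x)) NA_character_
                  else sprintf("%.17g", x), character(1))
      s
    } else as.character(col)
  }), stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- names(ds)
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

.has_raw_set <- function(ds) {
  eq3 <- !is.na(ds$delta_mbc) & !is.na(ds$delta_c_substrate)
  eq4 <- !is.na(ds$delta_mbc) & !is.na(ds$r_cumulative)
  eq5 <- !is.na(ds$delta_mbc) & !is.na(ds$resp_rate) & !is.na(ds$duration)
  eq3 | eq4 | eq5
}

#' Validate a CUE observation table
#'
#' Checks every record against the schema invariants and returns one issue
#' row per violation. Validation never raises on content: a malformed record
#' is reported, not fatal.
#'
#' Checked invariants: `cue`, when present, in the open interval (0, 1);
#' latitude in \[-90, 90\] and longitude in \[-180, 180\]; incubation
#' temperature within the \[-5, 45\] degC sanity bound; each record carries
#' either a reported `cue` or a complete raw-quantity set for one of the
#' three conversion formulas; `record_id` unique and non-missing.
#'
#' @param ds Observation data.frame in the standard schema.
#' @return data.frame with columns `record_id`, `field`, `message`; zero rows
#'   iff all invariants hold.
#' @export
validate_cue_dataset <- function(ds) {
  issues <- list()
  add <- function(idx, field, message) {
    if (length(idx) > 0)
      issues[[length(issues) + 1]] <<- data.frame(
        record_id = ifelse(is.na(ds$record_id[idx]), paste0("<row ", idx, ">"),
                           ds$record_id[idx]),
        field = field, message = message, stringsAsFactors = FALSE)
  }
  add(which(is.na(ds$record_id)), "record_id", "missing record identifier")
  dup <- ds$record_id[!is.na(ds$record_id)]
  dup <- unique(dup[duplicated(dup)])
  add(which(ds$record_id %in% dup), "record_id", "duplicated record identifier")
  add(which(!is.na(ds$cue) & (ds$cue <= 0 | ds$cue >= 1)), "cue",
      "cue out of (0,1)")
  add(which(!is.na(ds$latitude) & abs(ds$latitude) > 90), "latitude",
      "latitude outside [-90, 90]")
  add(which(!is.na(ds$longitude) & abs(ds$longitude) > 180), "longitude",
      "longitude outside [-180, 180]")
  add(which(!is.na(ds$incubation_temp) &
              (ds$incubation_temp < -5 | ds$incubation_temp > 45)),
      "incubation_temp", "incubation temperature outside [-5, 45] degC")
  add(which(is.na(ds$cue) & !.has_raw_set(ds)), "cue",
      "neither cue nor a complete raw-quantity set present")
  if (length(issues) == 0)
    return(data.frame(record_id = character(0), field = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}

#' Group-wise summary of CUE
#'
#' Mean and sample standard deviation (n-1 denominator) of non-missing CUE
#' per level of a grouping column, plus a pooled `"ALL"` row. Records missing
#' the grouping value are excluded from the group rows (their count is
#' attached as the `n_excluded` attribute) but still contribute to `"ALL"`.
#'
#' @param ds Observation data.frame.
#' @param grouping Name of the grouping column (e.g. `"pft"`,
#'   `"substrate_category"`).
#' @return data.frame with columns `group`, `n`, `mean`, `sd`; attribute
#'   `n_excluded` counts records with CUE but no group label.
#' @export
#' @examples
#' ds <- generate_cue_dataset(generator_config(n = 200, seed = 1))
#' summarize_cue_by(ds, "pft")
summarize_cue_by <- function(ds, grouping) {
  if (!grouping %in% names(ds)) stop("unknown grouping field: ", grouping)
  keep <- !is.na(ds$cue)
  cue <- ds$cue[keep]
  grp <- ds[[grouping]][keep]
  if (all(is.na(grp))) stop("grouping field '", grouping, "' has no values")
  in_group <- !is.na(grp)
  levels <- sort(unique(grp[in_group]))
  rows <- lapply(levels, function(g) {
    v <- cue[in_group & grp == g]
    data.frame(group = as.character(g), n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  rows[[length(rows) + 1]] <- data.frame(
    group = "ALL", n = length(cue), mean = mean(cue),
    sd = if (length(cue) > 1) stats::sd(cue) else NA_real_,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "n_excluded") <- sum(!in_group)
  out
}

#' Frequency table of CUE values
#'
#' Bins non-missing CUE into half-open intervals `[lo, lo + width)` tiling
#' `[0, 1)`, with the final bin closed at 1 so a value of exactly 1 is
#' counted.
#'
#' @param ds Observation data.frame.
#' @param bin_width Bin width in (0, 1]; default 0.1 gives ten bins.
#' @return data.frame with columns `bin_lower` and `count`; counts sum to the
#'   number of records with non-missing CUE in \[0, 1\].
#' @export
cue_histogram <- function(ds, bin_width = 0.1) {
  if (!is.numeric(bin_width) || length(bin_width) != 1 ||
      bin_width <= 0 || bin_width > 1)
    stop("bin_width must be a single value in (0, 1]")
  cue <- ds$cue[!is.na(ds$cue)]
  n_bins <- max(1L, ceiling(1 / bin_width - 1e-9))
  # signif() tidies accumulated float error so edges print as 0.3, not 0.30...04
  lowers <- signif(bin_width * (seq_len(n_bins) - 1), 12)
  # small tolerance so decimal values sitting on a bin edge (0.3/0.1 ->
  # 2.9999...) land in the bin they open, not the one below
  idx <- pmin(floor(cue / bin_width + 1e-9) + 1L, n_bins)  # last bin closed at 1
  idx <- idx[cue >= 0 & cue <= 1]
  counts <- tabulate(idx, nbins = n_bins)
  data.frame(bin_lower = lowers, count = counts)
}
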