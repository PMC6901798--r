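# On-disk formats. Single tabular dialect everywhere: UTF-8, tab-separated,
# '.' decimal, no quoting. Matrix files carry one leading comment line
# recording the value space.

#' Write / read a methylation matrix TSV
#'
#' The file starts with a comment line `#value_space=beta|M`, then a header
#' whose first cell names the probe-id column and whose remaining cells are
#' sample ids. Values are written with 6 decimals, so a write/read round trip
#' preserves values to 1e-6.
#'
#' @param matrix A [meth_matrix()].
#' @param path File path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns a
#'   [meth_matrix()].
#' @export
write_matrix <- function(matrix, path) {
  if (!inherits(matrix, "meth_matrix")) {
    mp_abort("`matrix` must be a meth_matrix", "mp_validation_error")
  }
  vals <- matrix$values
  body <- matrix(sprintf("%.6f", vals), nrow = nrow(vals))
  cols <- c(list(rownames(vals)), lapply(seq_len(ncol(vals)), function(j) body[, j]))
  lines <- c(
    sprintf("#value_space=%s", matrix$value_space),
    paste(c("probe_id", colnames(vals)), collapse = "\t"),
    do.call(paste, c(cols, sep = "\t"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) {
    mp_abort(sprintf("no such file: %s", path), "mp_format_error")
  }
  first <- readLines(path, n = 1L)
  skip <- 0L
  value_space <- "beta"
  if (startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec("^#value_space=(beta|M)$", first))[[1]]
    if (length(m) != 2L) {
      mp_abort(sprintf("unrecognised header comment: %s", first),
               "mp_format_error")
    }
    value_space <- m[2]
  }
  tab <- utils::read.delim(path, skip = skip, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           na.strings = NULL)
  if (ncol(tab) < 2L) {
    mp_abort("matrix file needs a probe-id column and at least one sample",
             "mp_format_error")
  }
  pid <- tab[[1]]
  vals <- matrix(NA_real_, nrow = nrow(tab), ncol = ncol(tab) - 1L,
                 dimnames = list(pid, colnames(tab)[-1]))
  for (j in seq_len(ncol(vals))) {
    cell <- tab[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num))
    if (length(bad)) {
      mp_abort(sprintf("non-numeric cell '%s' at row %d, column '%s'",
                       cell[bad[1]], bad[1], colnames(vals)[j]),
               "mp_format_error")
    }
    vals[, j] <- num
  }
  meth_matrix(vals, value_space)
}

#' Write / read a sample sheet TSV
#'
#' Header `sample_id<TAB>group<TAB>batch`, one row per sample.
#'
#' @param sheet A sample sheet data frame (see [sample_sheet()]).
#' @param path File path.
#' @return `write_sample_sheet` returns `path` invisibly; `read_sample_sheet`
#'   returns a validated data frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  sheet <- validate_sample_sheet(sheet)
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) {
    mp_abort(sprintf("no such file: %s", path), "mp_format_error")
  }
  validate_sample_sheet(utils::read.delim(path, colClasses = "character",
                                          na.strings = NULL))
}

#' Merge cohorts by common probes
#'
#' Combines several cohorts into one matrix over the intersection of their
#' probe sets (kept in the first cohort's order). Sample ids are prefixed
#' `"<cohort>:"` to guarantee global uniqueness and every sample's batch label
#' is set to its cohort name, so downstream batch adjustment removes
#' between-cohort shifts.
#'
#' @param matrices Named list (>= 2) of [meth_matrix()] objects in the same
#'   value space; names are the cohort names (or pass `cohort_names`).
#' @param sheets List of sample sheets parallel to `matrices`.
#' @param cohort_names Optional character vector of cohort names.
#' @return List with the merged `matrix` and `sheet`.
#' @export
merge_datasets <- function(matrices, sheets, cohort_names = names(matrices)) {
  if (!is.list(matrices) || length(matrices) < 2L) {
    mp_abort("need at least two cohorts to merge", "mp_merge_error")
  }
  if (length(sheets) != length(matrices)) {
    mp_abort("`sheets` must parallel `matrices`", "mp_merge_error")
  }
  if (is.null(cohort_names) || any(!nzchar(cohort_names)) ||
      anyDuplicated(cohort_names)) {
    mp_abort("cohorts must have unique non-empty names", "mp_merge_error")
  }
  spaces <- vapply(matrices, function(m) m$value_space, character(1))
  if (length(unique(spaces)) != 1L) {
    mp_abort("all cohorts must share one value space", "mp_merge_error")
  }
  common <- probe_ids(matrices[[1]])
  for (m in matrices[-1]) common <- common[common %in% probe_ids(m)]
  if (length(common) == 0L) {
    mp_abort("no probes are shared by all cohorts", "mp_merge_error")
  }
  vals <- vector("list", length(matrices))
  rows <- vector("list", length(matrices))
  for (i in seq_along(matrices)) {
    sh <- align_sheet(matrices[[i]], sheets[[i]])
    v <- matrices[[i]]$values[common, , drop = FALSE]
    colnames(v) <- paste0(cohort_names[i], ":", colnames(v))
    vals[[i]] <- v
    rows[[i]] <- data.frame(sample_id = colnames(v), group = sh$group,
                            batch = cohort_names[i], stringsAsFactors = FALSE)
  }
  merged_vals <- do.call(cbind, vals)
  if (anyDuplicated(colnames(merged_vals))) {
    mp_abort(sprintf("duplicated sample id after cohort prefixing: %s",
                     colnames(merged_vals)[duplicated(colnames(merged_vals))][1L]),
             "mp_merge_error")
  }
  list(matrix = meth_matrix(merged_vals, spaces[1]),
       sheet = validate_sample_sheet(do.call(rbind, rows)))
}

#' Per-cohort sample counts and totals
#'
#' Tabulates tumor/normal counts per batch label (one batch per cohort after
#' [merge_datasets()]) and overall totals.
#'
#' @param sheet A sample sheet.
#' @return A `cohort_manifest`: list with `per_cohort` (data frame `cohort`,
#'   `n_tumor`, `n_normal`) and totals `n_tumor`, `n_normal`, `n_all`.
#' @export
cohort_manifest <- function(sheet) {
  sheet <- validate_sample_sheet(sheet)
  cohorts <- unique(sheet$batch)
  per <- data.frame(
    cohort = cohorts,
    n_tumor = vapply(cohorts, function(b)
      sum(sheet$batch == b & sheet$group == "tumor"), integer(1)),
    n_normal = vapply(cohorts, function(b)
      sum(sheet$batch == b & sheet$group == "normal"), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(per_cohort = per,
                 n_tumor = sum(per$n_tumor),
                 n_normal = sum(per$n_normal),
                 n_all = sum(per$n_tumor) + sum(per$n_normal)),
            class = "cohort_manifest")
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cat("<cohort_manifest>\n")
  print(x$per_cohort, row.names = FALSE)
  cat(sprintf("totals: %d tumor / %d normal / %d samples\n",
              x$n_tumor, x$n_normal, x$n_all))
  invisible(x)
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "methpanel")
  if (!nzchar(p) || !file.exists(p)) {
    mp_abort(sprintf("packaged fixture '%s' is missing", file),
             "mp_packaging_error")
  }
  p
}

#' Published 62-probe differential methylation table
#'
#' Loads the packaged table of 62 differentially methylated probes reported
#' for the pooled 27k discovery cohorts (probe id, gene symbol, logFC and
#' BH-adjusted p-value, values exactly as printed to 2 decimals / 3
#' significant figures). `t` and `p` were not published and are `NA`.
#' Unicode minus signs are normalised to ASCII hyphens on ingest.
#'
#' @return A DMP table data frame (see [moderated_tests()] for the columns).
#' @export
load_table2_fixture <- function() {
  path <- fixture_path("dmp_reference_27k.tsv")
  tab <- utils::read.delim(path, colClasses = "character", na.strings = NULL)
  need <- c("probe_id", "symbol", "logFC", "adj_p")
  if (!all(need %in% names(tab))) {
    mp_abort("DMP fixture is corrupt: missing columns", "mp_packaging_error")
  }
  num <- function(x) as.numeric(gsub("−", "-", x))
  out <- data.frame(
    probe_id = tab$probe_id,
    symbol = ifelse(tab$symbol == "NA", NA_character_, tab$symbol),
    logFC = num(tab$logFC),
    t = NA_real_,
    p = NA_real_,
    adj_p = num(tab$adj_p),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$logFC) || anyNA(out$adj_p)) {
    mp_abort("DMP fixture is corrupt: non-numeric values", "mp_packaging_error")
  }
  out$direction <- ifelse(out$logFC > 0, "hyper", "hypo")
  out
}

#' Published discovery-cohort sample counts
#'
#' Loads the packaged per-cohort tumor/normal counts of the five 27k
#' discovery series.
#'
#' @return Data frame with columns `cohort`, `n_tumor`, `n_normal`.
#' @export
load_geo_cohort_counts <- function() {
  path <- fixture_path("geo_cohorts.tsv")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cohort", "n_tumor", "n_normal")
  if (!all(need %in% names(tab))) {
    mp_abort("cohort fixture is corrupt: missing columns", "mp_packaging_error")
  }
  tab[need]
}

#' Write a DMP table TSV
#'
#' Columns `probe_id`, `symbol`, `logFC`, `t`, `p`, `adj_p`, `direction`.
#'
#' @param table A DMP table.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_dmp_table <- function(table, path) {
  cols <- c("probe_id", "symbol", "logFC", "t", "p", "adj_p", "direction")
  missing_cols <- setdiff(cols, names(table))
  for (col in missing_cols) table[[col]] <- NA
  out <- table[cols]
  for (col in c("logFC", "t", "p", "adj_p")) {
    out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
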