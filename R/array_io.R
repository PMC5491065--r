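#' Read a single-array feature table
#'
#' Parses one array's tab-delimited feature-extraction export into a
#' `feature_scan`: probe id, control type (-1 negative control, 0 regular
#' probe, +1 positive control) and raw linear-scale signal. Column names
#' default to an Agilent-FE-like set and can be remapped for other
#' dialects.
#'
#' @param path path to a tab-delimited file with a header row.
#' @param array_id identifier for the scan; defaults to the file name
#'   without extension.
#' @param columns named character vector mapping the roles `probe`,
#'   `control` and `signal` to column names in the file.
#' @return A `feature_scan`: list with `array_id` and a data.frame
#'   `records` (`probe_id`, `control_type`, `raw_signal`), preserving the
#'   file's row order.
#' @export
read_feature_table <- function(path,
                               array_id = sub("\\.[^.]*$", "", basename(path)),
                               columns = c(probe = "ProbeName",
                                           control = "ControlType",
                                           signal = "gProcessedSignal")) {
  stopifnot(all(c("probe", "control", "signal") %in% names(columns)))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (role in c("probe", "control", "signal")) {
    if (!(columns[[role]] %in% names(tab))) {
      stop(sprintf("feature table '%s' lacks mandatory column '%s' (%s)",
                   path, columns[[role]], role))
    }
  }
  records <- data.frame(
    probe_id = as.character(tab[[columns[["probe"]]]]),
    control_type = as.integer(tab[[columns[["control"]]]]),
    raw_signal = as.numeric(tab[[columns[["signal"]]]]),
    stringsAsFactors = FALSE
  )
  if (nrow(records) > 0) {
    if (!all(records$control_type %in% c(-1L, 0L, 1L))) {
      bad <- which(!(records$control_type %in% c(-1L, 0L, 1L)))[1]
      stop(sprintf("row %d: control type must be -1, 0 or +1", bad))
    }
    if (any(neg <- records$raw_signal < 0)) {
      stop(sprintf("row %d: negative raw signal", which(neg)[1]))
    }
    if (anyDuplicated(records$probe_id)) {
      dup <- records$probe_id[duplicated(records$probe_id)][1]
      stop(sprintf("duplicate probe id '%s' within one array", dup))
    }
  }
  structure(list(array_id = array_id, records = records),
            class = "feature_scan")
}

#' Write a feature table (synthetic-data and round-trip support)
#'
#' @param scan a `feature_scan`.
#' @param path output path.
#' @param columns column names to write, same roles as
#'   [read_feature_table()].
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(scan, path,
                                columns = c(probe = "ProbeName",
                                            control = "ControlType",
                                            signal = "gProcessedSignal")) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(columns[["probe"]], columns[["control"]],
                   columns[["signal"]], sep = "\t"), con)
  if (nrow(scan$records) > 0) {
    writeLines(paste(scan$records$probe_id,
                     scan$records$control_type,
                     sprintf("%.17g", scan$records$raw_signal),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a sample sheet
#'
#' The sample sheet assigns each array to one of the three groups (ES, OS,
#' CSE) and optionally to a technical-duplicate pair. Comma- or
#' tab-delimited, chosen by file extension (`.csv` vs anything else).
#'
#' @param path path to the sheet. Columns: `sample_id`, `group`, optional
#'   `duplicate_pair_id` (empty string = unpaired).
#' @param group_aliases optional named character vector mapping
#'   nonstandard group labels to `"ES"`, `"OS"` or `"CSE"`.
#' @return A data.frame of class `"sample_sheet"` with columns
#'   `sample_id`, `group`, `duplicate_pair_id`.
#' @export
read_sample_sheet <- function(path, group_aliases = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (cl in c("sample_id", "group")) {
    if (!(cl %in% names(tab))) {
      stop(sprintf("sample sheet lacks mandatory column '%s'", cl))
    }
  }
  if (!("duplicate_pair_id" %in% names(tab))) tab$duplicate_pair_id <- ""
  tab$duplicate_pair_id[is.na(tab$duplicate_pair_id)] <- ""
  sample_sheet(sample_id = as.character(tab$sample_id),
               group = as.character(tab$group),
               duplicate_pair_id = as.character(tab$duplicate_pair_id),
               group_aliases = group_aliases)
}

#' Construct a validated sample sheet in memory
#'
#' @param sample_id character vector of unique array ids.
#' @param group group label per array (`"ES"`, `"OS"`, `"CSE"`, or an
#'   alias resolvable through `group_aliases`).
#' @param duplicate_pair_id technical-pair id per array (`""` =
#'   unpaired); each non-empty id must name exactly two samples.
#' @param group_aliases optional named character vector of label aliases.
#' @return A data.frame of class `"sample_sheet"`.
#' @export
sample_sheet <- function(sample_id, group,
                         duplicate_pair_id = rep("", length(sample_id)),
                         group_aliases = NULL) {
  if (anyDuplicated(sample_id)) {
    stop(sprintf("duplicate sample id '%s' in sample sheet",
                 sample_id[duplicated(sample_id)][1]))
  }
  if (!is.null(group_aliases)) {
    hit <- group %in% names(group_aliases)
    group[hit] <- group_aliases[group[hit]]
  }
  bad <- setdiff(unique(group), GROUPS)
  if (length(bad) > 0) {
    stop(sprintf("unknown group label '%s' (expected ES, OS or CSE)", bad[1]))
  }
  pid <- duplicate_pair_id
  for (p in setdiff(unique(pid), "")) {
    if (sum(pid == p) != 2) {
      stop(sprintf("duplicate pair '%s' must name exactly 2 samples", p))
    }
  }
  structure(data.frame(sample_id = sample_id, group = group,
                       duplicate_pair_id = pid, stringsAsFactors = FALSE),
            class = c("sample_sheet", "data.frame"))
}

#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Assemble per-array scans into a raw expression matrix
#'
#' Every sample in the sheet must have exactly one scan and all scans
#' must share the same probe set. Column order follows the sheet.
#'
#' @param scans list of `feature_scan` objects.
#' @param sheet a `sample_sheet`; `sample_id` must match scan
#'   `array_id`s.
#' @return list with `matrix` (an `expr_matrix`, stage `"raw"`, scale
#'   `"linear"`, probes in the first scan's row order) and
#'   `control_types` (named integer vector shared across arrays).
#' @export
assemble_matrix <- function(scans, sheet) {
  ids <- vapply(scans, function(s) s$array_id, character(1))
  missing <- setdiff(sheet$sample_id, ids)
  if (length(missing) > 0) {
    stop(sprintf("no scan for sample '%s'", missing[1]))
  }
  scans <- scans[match(sheet$sample_id, ids)]
  ref <- scans[[1]]$records$probe_id
  for (s in scans[-1]) {
    if (!setequal(s$records$probe_id, ref)) {
      d <- c(setdiff(ref, s$records$probe_id),
             setdiff(s$records$probe_id, ref))
      stop(sprintf("probe sets differ across arrays; first differing ids: %s",
                   paste(utils::head(d, 10), collapse = ", ")))
    }
  }
  values <- vapply(scans, function(s) {
    s$records$raw_signal[match(ref, s$records$probe_id)]
  }, numeric(length(ref)))
  values <- matrix(values, nrow = length(ref),
                   dimnames = list(ref, sheet$sample_id))
  ct <- scans[[1]]$records$control_type
  names(ct) <- ref
  list(matrix = expr_matrix(values, scale = "linear", stage = "raw"),
       control_types = ct)
}

#' Write / read an expression matrix as TSV
#'
#' Plain tab-delimited text: two comment lines carrying scale and stage,
#' a header of sample ids, probe ids in the first column, values rendered
#' at full precision so that `read_matrix(write_matrix(x))` reproduces
#' `x` exactly (values, ordering and metadata).
#'
#' @param m an `expr_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  check_matrix_state(m, what = "matrix")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# scale: %s", m$scale),
               sprintf("# stage: %s", m$stage),
               paste(c("probe_id", colnames(m$values)), collapse = "\t")),
             con)
  if (nrow(m$values) > 0) {
    body <- apply(m$values, 1, function(row) {
      paste(sprintf("%.17g", row), collapse = "\t")
    })
    writeLines(paste(rownames(m$values), body, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grep("^#", lines, value = TRUE)
  scale <- sub("^# scale: *", "", grep("^# scale:", meta, value = TRUE))
  stage <- sub("^# stage: *", "", grep("^# stage:", meta, value = TRUE))
  if (length(scale) != 1 || length(stage) != 1) {
    stop("matrix file lacks '# scale:' / '# stage:' metadata lines")
  }
  body <- lines[!grepl("^#", lines)]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "probe_id") stop("matrix file header must start with 'probe_id'")
  samples <- header[-1]
  rows <- body[-1]
  rows <- rows[nzchar(rows)]
  values <- matrix(numeric(0), nrow = 0, ncol = length(samples),
                   dimnames = list(NULL, samples))
  if (length(rows) > 0) {
    parts <- strsplit(rows, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != length(header))) {
      stop(sprintf("row %d has %d fields, expected %d",
                   which(nf != length(header))[1],
                   nf[nf != length(header)][1], length(header)))
    }
    pm <- do.call(rbind, parts)
    values <- matrix(as.numeric(pm[, -1, drop = FALSE]),
                     nrow = nrow(pm),
                     dimnames = list(pm[, 1], samples))
  }
  expr_matrix(values, scale = scale, stage = stage)
}

#' Read / write a probe annotation table
#'
#' Tab-delimited: `probe_id`, `gene_symbol`, `go_ids` with GO accessions
#' separated by semicolons (empty allowed).
#'
#' @param path file path.
#' @return data.frame of class `"annotation_table"` with columns
#'   `probe_id`, `gene_symbol` and a list column `go_ids`.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  for (cl in c("probe_id", "gene_symbol", "go_ids")) {
    if (!(cl %in% names(tab))) {
      stop(sprintf("annotation table lacks column '%s'", cl))
    }
  }
  annotation_table(tab$probe_id, tab$gene_symbol,
                   strsplit(ifelse(is.na(tab$go_ids), "", tab$go_ids), ";",
                            fixed = TRUE))
}

#' @rdname read_annotation
#' @param probe_id,gene_symbol character vectors, one entry per probe.
#' @param go_ids list of character vectors of GO accessions (may be
#'   empty).
#' @export
annotation_table <- function(probe_id, gene_symbol, go_ids) {
  if (anyDuplicated(probe_id)) {
    stop("duplicate probe ids in annotation table")
  }
  go_ids <- lapply(go_ids, function(g) g[nzchar(g)])
  out <- data.frame(probe_id = as.character(probe_id),
                    gene_symbol = as.character(gene_symbol),
                    stringsAsFactors = FALSE)
  out$go_ids <- go_ids
  structure(out, class = c("annotation_table", "data.frame"))
}

#' @rdname read_annotation
#' @param ann an `annotation_table`.
#' @export
write_annotation <- function(ann, path) {
  flat <- data.frame(probe_id = ann$probe_id,
                     gene_symbol = ann$gene_symbol,
                     go_ids = vapply(ann$go_ids, paste, character(1),
                                     collapse = ";"),
                     stringsAsFactors = FALSE)
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a GEO-style series matrix
#'
#' Minimal dialect support for reanalysis of deposited arrays: metadata
#' lines start with `!`, the value table sits between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`, first
#' column `ID_REF`, remaining columns one per sample. Series matrices are
#' post-processing deposits, so the result is at stage `"normalized"`;
#' the scale is not recorded in the format and must be supplied.
#'
#' @param path file path.
#' @param scale scale of the deposited values, `"log2"` (common) or
#'   `"linear"`.
#' @return an `expr_matrix` at stage `"normalized"`.
#' @export
read_series_matrix <- function(path, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  lines <- readLines(path, encoding = "UTF-8")
  beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  fin <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(beg) != 1 || length(fin) != 1 || fin <= beg) {
    stop("series matrix lacks table begin/end markers")
  }
  tab <- lines[(beg + 1):(fin - 1)]
  unquote <- function(x) gsub('^"|"$', "", x)
  header <- unquote(strsplit(tab[1], "\t", fixed = TRUE)[[1]])
  samples <- header[-1]
  rows <- tab[-1]
  values <- matrix(numeric(0), nrow = 0, ncol = length(samples),
                   dimnames = list(NULL, samples))
  if (length(rows) > 0) {
    parts <- lapply(strsplit(rows, "\t", fixed = TRUE), unquote)
    pm <- do.call(rbind, parts)
    values <- matrix(as.numeric(pm[, -1, drop = FALSE]), nrow = nrow(pm),
                     dimnames = list(pm[, 1], samples))
  }
  expr_matrix(values, scale = scale, stage = "normalized")
}

#' @rdname read_series_matrix
#' @param m an `expr_matrix` at stage `"normalized"`.
#' @export
write_series_matrix <- function(m, path) {
  check_matrix_state(m, stage = "normalized", what = "matrix")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("!Series_title\t\"synthetic series\"",
               "!series_matrix_table_begin",
               paste(c("\"ID_REF\"",
                       sprintf('"%s"', colnames(m$values))), collapse = "\t")),
             con)
  if (nrow(m$values) > 0) {
    body <- apply(m$values, 1, function(row) {
      paste(sprintf("%.17g", row), collapse = "\t")
    })
    writeLines(paste(sprintf('"%s"', rownames(m$values)), body, sep = "\t"),
               con)
  }
  writeLines("!series_matrix_table_end", con)
  invisible(path)
}
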