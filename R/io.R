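# Plain-text readers/writers for the pipeline dialects. All readers
# validate field-by-field and report parse errors with file, line (1-based,
# counting the header) and field name.

parse_error <- function(path, line, field, msg) {
  stop(sprintf("parse error in %s:%d, field '%s': %s", path, line, field,
               msg), call. = FALSE)
}

as_numeric_col <- function(x, field, path, header_lines = 1L) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    parse_error(path, bad[1L] + header_lines, field,
                sprintf("'%s' is not numeric", x[bad[1L]]))
  v
}

read_delim_checked <- function(path, need, sep, header = TRUE) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  if (header && !all(need %in% names(df)))
    stop_input("%s: missing column(s) %s", path,
               paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' Read / write a pneumotachograph trace CSV
#'
#' Trace CSV columns: `time_s`, `pressure_mv`, `temperature_c`. The
#' sampling rate is recovered from the time column (which must be a uniform
#' grid). Optional epoch and artifact-mask CSVs share the interval dialect
#' of [read_intervals_csv()].
#'
#' @param path trace CSV path.
#' @param epochs_path,mask_path optional interval CSV paths.
#' @return A [pressure_trace()].
#' @export
read_trace_csv <- function(path, epochs_path = NULL, mask_path = NULL) {
  df <- read_delim_checked(path, c("time_s", "pressure_mv",
                                   "temperature_c"), ",")
  t <- as_numeric_col(df$time_s, "time_s", path)
  v <- as_numeric_col(df$pressure_mv, "pressure_mv", path)
  tc <- as_numeric_col(df$temperature_c, "temperature_c", path)
  if (length(t) < 2L) stop_input("%s: trace needs >= 2 samples", path)
  dt <- diff(t)
  if (max(abs(dt - dt[1L])) > 1e-6 * dt[1L])
    parse_error(path, which.max(abs(dt - dt[1L])) + 2L, "time_s",
                "time grid is not uniform")
  epochs <- if (!is.null(epochs_path)) read_intervals_csv(epochs_path)
  mask <- if (!is.null(mask_path)) read_intervals_csv(mask_path)
  ep <- if (!is.null(epochs))
    data.frame(label = epochs$label, start_s = epochs$start_s,
               end_s = epochs$end_s)
  pressure_trace(v, 1 / dt[1L], epochs = ep, artifact_mask = mask,
                 temperature_c = tc)
}

#' @rdname read_trace_csv
#' @param trace a [pressure_trace()] to serialize.
#' @export
write_trace_csv <- function(trace, path) {
  n <- length(trace$samples)
  df <- data.frame(
    time_s = (seq_len(n) - 1L) / trace$sampling_rate_hz,
    pressure_mv = trace$samples,
    temperature_c = if (is.null(trace$temperature_c)) rep(NA_real_, n)
                    else trace$temperature_c)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an interval CSV (artifact masks, condition epochs)
#'
#' Columns: `start_s`, `end_s`, `label`. Intervals are half-open seconds.
#'
#' @param path CSV path.
#' @return `data.frame` with `start_s`, `end_s`, `label`.
#' @export
read_intervals_csv <- function(path) {
  df <- read_delim_checked(path, c("start_s", "end_s", "label"), ",")
  s <- as_numeric_col(df$start_s, "start_s", path)
  e <- as_numeric_col(df$end_s, "end_s", path)
  bad <- which(s >= e)
  if (length(bad))
    parse_error(path, bad[1L] + 1L, "end_s", "start_s >= end_s")
  data.frame(start_s = s, end_s = e, label = as.character(df$label),
             stringsAsFactors = FALSE)
}

#' @rdname read_intervals_csv
#' @param intervals `data.frame` with `start_s`, `end_s` and optional
#'   `label`.
#' @export
write_intervals_csv <- function(intervals, path) {
  df <- as.data.frame(intervals)
  if (is.null(df$label)) df$label <- ""
  utils::write.csv(df[c("start_s", "end_s", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an expression matrix TSV with its sample-group sidecar
#'
#' Matrix TSV: `gene_id` column plus one numeric column per sample. Groups
#' TSV: `sample_id`, `group` (`case`/`control`).
#'
#' @param path expression TSV path.
#' @param groups_path sample-group sidecar TSV path.
#' @return List with `values` (genes x samples matrix, gene ids as row
#'   names) and `groups` (character vector aligned to columns).
#' @export
read_expression_tsv <- function(path, groups_path) {
  df <- read_delim_checked(path, "gene_id", "\t")
  if (ncol(df) < 3L) stop_input("%s: need gene_id + >= 2 samples", path)
  if (anyDuplicated(df$gene_id))
    stop_input("%s: duplicate gene_id", path)
  vals <- sapply(names(df)[-1L], function(cn)
    as_numeric_col(df[[cn]], cn, path))
  rownames(vals) <- df$gene_id
  g <- read_delim_checked(groups_path, c("sample_id", "group"), "\t")
  if (!setequal(g$sample_id, colnames(vals)))
    stop_input("%s: sample ids do not match matrix columns", groups_path)
  groups <- g$group[match(colnames(vals), g$sample_id)]
  if (!all(groups %in% c("case", "control")))
    parse_error(groups_path, which(!g$group %in% c("case", "control"))[1L] + 1L,
                "group", "must be 'case' or 'control'")
  list(values = vals, groups = groups)
}

#' @rdname read_expression_tsv
#' @param values genes x samples matrix with dimnames.
#' @param groups character vector of `case`/`control` per column.
#' @export
write_expression_tsv <- function(values, groups, path, groups_path) {
  df <- data.frame(gene_id = rownames(values), values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(data.frame(sample_id = colnames(values),
                                group = groups),
                     groups_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write BED3 peak files
#'
#' Standard headerless BED: `chrom`, `start`, `end`, 0-based half-open,
#' `start < end` enforced per row.
#'
#' @param path BED file path.
#' @return `data.frame` with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    parse_error(path, which(nf < 3L)[1L], "end", "fewer than 3 fields")
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as_numeric_col(vapply(parts, `[[`, "", 2L), "start", path,
                          header_lines = 0L)
  end <- as_numeric_col(vapply(parts, `[[`, "", 3L), "end", path,
                        header_lines = 0L)
  bad <- which(start >= end)
  if (length(bad))
    parse_error(path, bad[1L], "end", "start >= end")
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' @rdname read_bed
#' @param peaks `data.frame` with `chrom`, `start`, `end`.
#' @export
write_bed <- function(peaks, path) {
  df <- as.data.frame(peaks)[c("chrom", "start", "end")]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a gene-TSS annotation TSV
#'
#' Columns: `gene_id`, `chrom`, `strand` (`+`/`-`), `tss_0based`.
#'
#' @param path TSV path.
#' @return `data.frame` with `gene_id`, `chrom`, `strand`, `tss`.
#' @export
read_gene_annot <- function(path) {
  df <- read_delim_checked(path, c("gene_id", "chrom", "strand",
                                   "tss_0based"), "\t")
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad))
    parse_error(path, bad[1L] + 1L, "strand", "must be '+' or '-'")
  tss <- as_numeric_col(df$tss_0based, "tss_0based", path)
  if (anyDuplicated(df$gene_id)) stop_input("%s: duplicate gene_id", path)
  data.frame(gene_id = df$gene_id, chrom = df$chrom, strand = df$strand,
             tss = tss, stringsAsFactors = FALSE)
}

#' @rdname read_gene_annot
#' @param genes `data.frame` with `gene_id`, `chrom`, `strand`, `tss`.
#' @export
write_gene_annot <- function(genes, path) {
  df <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                   strand = genes$strand,
                   tss_0based = format(genes$tss, scientific = FALSE,
                                       trim = TRUE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
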