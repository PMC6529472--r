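#' Read and write migration tracks as TSV
#'
#' The on-disk format is tab-separated with columns
#' `cell_id  t_h  x_um  y_um`. The reader tolerates ImageJ-style tracking
#' exports by sniffing the header: any file whose header contains columns
#' recognizable as track id, time/frame and x/y (case-insensitive, e.g.
#' MTrack2's `Nr`, `Frame`, `X`, `Y`) is accepted; a frame column is
#' converted to hours with `frame_interval_h`.
#'
#' @param path File path.
#' @param frame_interval_h Hours per frame when the file has a frame column
#'   instead of a time column (default 0.5, a 30-minute interval).
#' @return `read_tracks_tsv` returns a list of [track()] objects;
#'   `write_tracks_tsv` writes and returns `path` invisibly.
#' @export
read_tracks_tsv <- function(path, frame_interval_h = 0.5) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  pick <- function(cands) {
    i <- which(nm %in% cands)[1]
    if (is.na(i)) NA_integer_ else i
  }
  id_col <- pick(c("cell_id", "track", "track_id", "nr", "id"))
  t_col <- pick(c("t_h", "t", "time", "time_h"))
  f_col <- pick(c("frame", "slice"))
  x_col <- pick(c("x_um", "x"))
  y_col <- pick(c("y_um", "y"))
  if (is.na(id_col) || is.na(x_col) || is.na(y_col) ||
      (is.na(t_col) && is.na(f_col))) {
    stop("unrecognized track file header: ", paste(names(df), collapse = ", "),
         call. = FALSE)
  }
  tvals <- if (!is.na(t_col)) df[[t_col]] else (df[[f_col]] - min(df[[f_col]])) * frame_interval_h
  ids <- as.character(df[[id_col]])
  lapply(split(seq_len(nrow(df)), ids), function(rows) {
    ord <- rows[order(tvals[rows])]
    track(ids[ord[1]], tvals[ord], df[[x_col]][ord], df[[y_col]][ord])
  })
}

#' @rdname read_tracks_tsv
#' @param tracks List of [track()] objects.
#' @export
write_tracks_tsv <- function(tracks, path) {
  df <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(cell_id = tr$cell_id, t_h = tr$t, x_um = tr$x, y_um = tr$y)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write nucleus spot tables as TSV
#'
#' Columns: `cell_id  x_um  y_um  z_um` (z = 0 at the gel surface,
#' positive = deeper).
#'
#' @param path File path.
#' @return `read_spots_tsv` returns a `spot_set`; the writer returns `path`
#'   invisibly.
#' @export
read_spots_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  spot_set(df[c("x_um", "y_um", "z_um")], source = "provided")
}

#' @rdname read_spots_tsv
#' @param spots A `spot_set`.
#' @export
write_spots_tsv <- function(spots, path) {
  df <- spots$spots
  df <- cbind(cell_id = sprintf("cell_%04d", seq_len(nrow(df))), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write expression matrices as TSV
#'
#' Genes in rows (first column `gene`), samples in columns named
#' `t<h>_rep<k>` (e.g. `t0_rep1`, `t48_rep3`); timepoints are parsed from
#' the column names.
#'
#' @param path File path.
#' @return `read_expression_tsv` returns an [expression_matrix()]; the
#'   writer returns `path` invisibly.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- genes
  tps <- as.numeric(sub("^t([0-9.]+)_rep[0-9]+$", "\\1", colnames(m)))
  if (any(is.na(tps))) {
    stop("column names must look like t<h>_rep<k>", call. = FALSE)
  }
  expression_matrix(m, tps)
}

#' @rdname read_expression_tsv
#' @param expr An [expression_matrix()].
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a curated gene-set file
#'
#' Plain text, one gene per line; the first line is the set name.
#'
#' @param path File path.
#' @return A list with `name` and unique `members`.
#' @export
read_gene_set <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("gene-set file needs a name line and members",
                              call. = FALSE)
  list(name = lines[1], members = unique(lines[-1]))
}

#' Write a bootstrap curve as CSV
#'
#' Columns `t_s, eps_bs, ci_halfwidth`.
#'
#' @param curve A `bootstrap_curve`.
#' @param path Output path.
#' @export
write_bootstrap_curve_csv <- function(curve, path) {
  write.csv(data.frame(t_s = curve$t, eps_bs = curve$epsilon_bs,
                       ci_halfwidth = curve$ci_halfwidth),
            path, row.names = FALSE)
  invisible(path)
}

#' @importFrom utils read.csv write.csv
NULL
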