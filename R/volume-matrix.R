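#' Participants-by-subregions volume matrix
#'
#' The basic data container of the package: a numeric matrix of per-participant
#' subregion volumes together with per-column anatomy metadata (structure,
#' hemisphere, subfield/lobe category, head/body portion). Rows are
#' participants (rownames are participant ids), columns are subregions.
#'
#' @param data Numeric matrix, participants x subregions. Must have rownames
#'   (participant ids) and colnames (subregion ids).
#' @param anatomy Data.frame with one row per column of `data`, carrying at
#'   least `subregion`, `structure`, `hemisphere`, `category` (and optionally
#'   `part`). Defaults to [hc_atlas()] / [dn_atlas()] lookups by column name.
#' @return An object of class `volume_matrix`.
#' @export
volume_matrix <- function(data, anatomy) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix")
  if (is.null(rownames(data)))
    rownames(data) <- paste0("P", seq_len(nrow(data)))
  if (is.null(colnames(data)))
    stop("`data` must have subregion column names")
  if (anyNA(data) || any(!is.finite(data)))
    stop("volume matrix contains missing or non-finite values")
  if (missing(anatomy)) {
    atlas <- rbind(hc_atlas(), dn_atlas())
    anatomy <- atlas[match(colnames(data), atlas$subregion), ]
    if (anyNA(anatomy$subregion))
      stop("no default anatomy for subregions: ",
           paste(setdiff(colnames(data), atlas$subregion), collapse = ", "))
  }
  need <- c("subregion", "structure", "hemisphere", "category")
  if (!all(need %in% names(anatomy)))
    stop("anatomy must have columns: ", paste(need, collapse = ", "))
  if (!"part" %in% names(anatomy)) anatomy$part <- NA_character_
  if (nrow(anatomy) != ncol(data) ||
      !identical(anatomy$subregion, colnames(data)))
    stop("anatomy rows must match data columns one-to-one, in order")
  rownames(anatomy) <- NULL
  structure(list(data = data, anatomy = anatomy), class = "volume_matrix")
}

#' @export
print.volume_matrix <- function(x, ...) {
  cat(sprintf("volume_matrix: %d participants x %d subregions (%s)\n",
              nrow(x$data), ncol(x$data),
              paste(unique(x$anatomy$structure), collapse = "+")))
  invisible(x)
}

#' @export
dim.volume_matrix <- function(x) dim(x$data)

#' Extract the numeric matrix from a volume matrix
#'
#' @param x A `volume_matrix` (plain matrices pass through).
#' @return The underlying participants x subregions numeric matrix.
#' @export
as_matrix <- function(x) {
  if (inherits(x, "volume_matrix")) x$data else as.matrix(x)
}

participant_ids <- function(x) rownames(as_matrix(x))

vm_like <- function(template, data) {
  volume_matrix(data, anatomy = template$anatomy)
}

#' Read / write volume matrices as TSV
#'
#' The TSV layout is a `participant_id` key column followed by one column per
#' subregion. Anatomy metadata is resolved from the default atlases unless an
#' `anatomy` table is supplied at read time.
#'
#' @param x A `volume_matrix`.
#' @param path TSV file path.
#' @param anatomy Optional anatomy data.frame (see [volume_matrix()]).
#' @return `read_volume_tsv` returns a `volume_matrix`; `write_volume_tsv`
#'   returns `path` invisibly.
#' @export
write_volume_tsv <- function(x, path) {
  m <- as_matrix(x)
  df <- data.frame(participant_id = rownames(m), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_volume_tsv
#' @export
read_volume_tsv <- function(path, anatomy) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"participant_id" %in% names(df))
    stop("volume TSV must carry a participant_id column: ", path)
  m <- as.matrix(df[, setdiff(names(df), "participant_id"), drop = FALSE])
  rownames(m) <- df$participant_id
  if (missing(anatomy)) volume_matrix(m) else volume_matrix(m, anatomy)
}
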