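#' Anatomical hit-count table
#'
#' A modes x categories table of nonnegative hit counts with double-entry
#' margins: per-category totals, per-mode totals and the grand total are
#' always recomputed from the cells. A separately printed total row (as
#' published tables sometimes carry one that disagrees with its own cells) can
#' be attached verbatim via `printed_totals` without ever overriding the
#' computed margins.
#'
#' @param counts Integer matrix, modes x categories (dimnames required on
#'   columns; row names default to mode numbers).
#' @param printed_totals Optional named vector: a total row as printed in a
#'   source table, kept for comparison only.
#' @return An object of class `hit_table`.
#' @export
hit_table <- function(counts, printed_totals = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("hit counts must be nonnegative integers")
  if (is.null(colnames(counts))) stop("counts must have category column names")
  if (is.null(rownames(counts))) rownames(counts) <- seq_len(nrow(counts))
  structure(list(counts = counts,
                 category_totals = colSums(counts),
                 mode_totals = rowSums(counts),
                 grand_total = sum(counts),
                 printed_totals = printed_totals),
            class = "hit_table")
}

#' @export
print.hit_table <- function(x, ...) {
  m <- rbind(x$counts, Total = x$category_totals)
  print(cbind(m, Total = c(x$mode_totals, x$grand_total)))
  invisible(x)
}

#' Derived percentage shares of a hit table
#'
#' Mode and category shares of the grand total, as raw fractions times 100.
#' With an all-zero table every share is `NA` (undefined, not 0/0).
#'
#' @param x A [hit_table()].
#' @return List with `mode_share_pct` and `category_share_pct`.
#' @export
hit_shares <- function(x) {
  if (x$grand_total == 0)
    return(list(mode_share_pct = stats::setNames(
      rep(NA_real_, nrow(x$counts)), rownames(x$counts)),
      category_share_pct = stats::setNames(
        rep(NA_real_, ncol(x$counts)), colnames(x$counts))))
  list(mode_share_pct = 100 * x$mode_totals / x$grand_total,
       category_share_pct = 100 * x$category_totals / x$grand_total)
}

hc_category_order <- c("CA1", "CA2/3", "CA4", "DG", "HATA", "Para", "PrS",
                       "Sub", "Fissure", "Fimbria", "ML", "Tail")
dn_category_order <- c("Temporal", "Prefrontal", "Parietal",
                       "Posterior cingulate")

#' Tally hits by anatomical category, per structure
#'
#' Counts hit flags per mode and per anatomical category, separately for the
#' HC view (12 subfield groups) and the DN view (4 lobe groups), in the
#' conventional column orders. Every subregion must map to exactly one
#' category.
#'
#' @param x A `contrast_result`, or a logical k x (p+q) hit matrix whose
#'   columns follow `anatomy`.
#' @param anatomy Anatomy data.frame (taken from the result when `x` is a
#'   `contrast_result`).
#' @param ... Unused.
#' @return List with elements `hc` and `dn`, each a [hit_table()].
#' @export
tally_hits <- function(x, ...) UseMethod("tally_hits")

#' @rdname tally_hits
#' @export
tally_hits.contrast_result <- function(x, ...) {
  tally_hits(x$hit_flags, anatomy = x$anatomy)
}

#' @rdname tally_hits
#' @export
tally_hits.matrix <- function(x, anatomy, ...) {
  if (ncol(x) != nrow(anatomy))
    stop("hit matrix columns and anatomy rows must match")
  bad <- is.na(anatomy$category) | !nzchar(anatomy$category)
  if (any(bad))
    stop("unmapped subregion(s): ",
         paste(anatomy$subregion[bad], collapse = ", "))
  one <- function(struct, order) {
    take <- anatomy$structure == struct
    raw <- anatomy$category[take]
    # canonical column order when the categories follow the default scheme;
    # otherwise the categories define their own columns
    lev <- if (all(raw %in% order)) order else sort(unique(raw))
    cats <- factor(raw, levels = lev)
    sub <- x[, take, drop = FALSE]
    counts <- matrix(0L, nrow(x), nlevels(cats),
                     dimnames = list(seq_len(nrow(x)), levels(cats)))
    for (l in seq_len(nrow(x)))
      counts[l, ] <- as.integer(table(cats[sub[l, ] == TRUE]))
    hit_table(counts)
  }
  list(hc = one("HC", hc_category_order), dn = one("DN", dn_category_order))
}

#' Hemisphere tally of hits over a mode subset
#'
#' Counts hits per hemisphere (optionally restricted to one structure and a
#' subset of modes) and reports the left-hemisphere share.
#'
#' @param x A `contrast_result` or logical hit matrix.
#' @param anatomy Anatomy table (from the result if omitted).
#' @param modes Integer mode subset (default all).
#' @param structure `"both"` (default), `"HC"` or `"DN"`.
#' @return List with `left`, `right`, `total` counts and `left_share_pct`
#'   (`NA` when no hits).
#' @export
laterality_summary <- function(x, anatomy = NULL, modes = NULL,
                               structure = c("both", "HC", "DN")) {
  structure <- match.arg(structure)
  if (inherits(x, "contrast_result")) { anatomy <- x$anatomy; x <- x$hit_flags }
  if (is.null(anatomy)) stop("anatomy metadata required")
  if (is.null(modes)) modes <- seq_len(nrow(x))
  if (anyNA(anatomy$hemisphere)) stop("hemisphere metadata incomplete")
  take <- if (structure == "both") rep(TRUE, nrow(anatomy))
          else anatomy$structure == structure
  h <- x[modes, take, drop = FALSE]
  hemi <- anatomy$hemisphere[take]
  left <- sum(h[, hemi == "L", drop = FALSE])
  right <- sum(h[, hemi == "R", drop = FALSE])
  total <- left + right
  list(left = left, right = right, total = total,
       left_share_pct = if (total == 0) NA_real_ else 100 * left / total)
}

#' Head/body tally of HC hits
#'
#' Counts HC hits in head vs body portions over a mode subset; subregions
#' without a head/body label (the fissure) are excluded from the shares.
#'
#' @inheritParams laterality_summary
#' @return List with `head`, `body`, `total` and `head_share_pct`.
#' @export
head_body_summary <- function(x, anatomy = NULL, modes = NULL) {
  if (inherits(x, "contrast_result")) { anatomy <- x$anatomy; x <- x$hit_flags }
  if (is.null(anatomy)) stop("anatomy metadata required")
  if (is.null(modes)) modes <- seq_len(nrow(x))
  take <- anatomy$structure == "HC" & !is.na(anatomy$part)
  h <- x[modes, take, drop = FALSE]
  part <- anatomy$part[take]
  head_n <- sum(h[, part == "head", drop = FALSE])
  body_n <- sum(h[, part == "body", drop = FALSE])
  total <- head_n + body_n
  list(head = head_n, body = body_n, total = total,
       head_share_pct = if (total == 0) NA_real_ else 100 * head_n / total)
}

#' Turn a long (mode, subregion) hit listing into a hit-flag matrix
#'
#' @param df Data.frame with `mode` and `subregion` columns, one row per hit.
#' @param anatomy Anatomy table defining the column universe and order.
#' @param k Number of modes (rows); defaults to `max(df$mode)`.
#' @return Logical k x nrow(anatomy) matrix.
#' @export
hit_flag_matrix <- function(df, anatomy, k = max(df$mode)) {
  unknown <- setdiff(df$subregion, anatomy$subregion)
  if (length(unknown))
    stop("hits reference unknown subregions: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  m <- matrix(FALSE, k, nrow(anatomy),
              dimnames = list(paste0("mode", seq_len(k)), anatomy$subregion))
  m[cbind(df$mode, match(df$subregion, anatomy$subregion))] <- TRUE
  m
}

#' Read a published mode-by-category hit-count table
#'
#' Reads a TSV encoding of a printed hit table: a `mode` column with numeric
#' mode rows plus one `Total` row (the total row as printed, which is kept
#' separate and never trusted over the cells), and one column per category.
#'
#' @param path TSV path.
#' @return A [hit_table()] with `printed_totals` attached.
#' @export
read_published_hit_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  tot <- df$mode == "Total"
  cells <- as.matrix(df[!tot, -1, drop = FALSE])
  rownames(cells) <- df$mode[!tot]
  printed <- if (any(tot)) unlist(df[tot, -1, drop = TRUE]) else NULL
  hit_table(cells, printed_totals = printed)
}

#' Render a hit table as Markdown
#'
#' @param x A [hit_table()].
#' @param caption Optional caption line.
#' @return Character scalar of Markdown.
#' @export
format_hit_table <- function(x, caption = NULL) {
  m <- rbind(x$counts, Total = x$category_totals)
  m <- cbind(m, Total = c(x$mode_totals, x$grand_total))
  header <- paste0("| Mode | ", paste(colnames(m), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(m) + 1), collapse = "|"), "|")
  rows <- vapply(rownames(m), function(r)
    paste0("| ", r, " | ", paste(m[r, ], collapse = " | "), " |"), character(1))
  md <- paste(c(if (!is.null(caption)) paste0("**", caption, "**\n"),
                header, sep, rows), collapse = "\n")
  paste0(md, "\n")
}

#' Write the HC/DN hit-table pair as TSV
#'
#' @param tables A list as returned by [tally_hits()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_hit_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    x <- tables[[nm]]
    df <- data.frame(mode = c(rownames(x$counts), "Total"),
                     rbind(x$counts, x$category_totals),
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0(nm, "_hits.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
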