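#' Match two CCA solutions mode-by-mode in order and sign
#'
#' Mode order and sign are not identifiable across CCA refits: a resampled fit
#' may return the "same" modes shuffled and/or with flipped signs. This
#' builds the k x k similarity matrix whose (l, m) entry is the absolute
#' Pearson correlation between the concatenated canonical vectors
#' `[v_l; u_l]` of the reference and `[v_m; u_m]` of the other solution (a
#' mode is matched by its full two-view anatomical signature), solves the
#' assignment problem maximizing total similarity (optimal linear assignment,
#' not greedy, so near-tied neighboring modes cannot cascade into
#' mismatches), and sets sign -1 wherever the signed correlation of a matched
#' pair is negative.
#'
#' Matched pairs with similarity below `flag_threshold` are flagged as
#' low-quality; downstream consumers may drop or keep them (they are kept and
#' counted by default).
#'
#' @param reference,other Two [fit_cca()] solutions sharing `k` and identical
#'   subregion column sets.
#' @param flag_threshold Similarity below which a match is flagged
#'   (default 0.5).
#' @return An object of class `mode_match`: `permutation` (index in `other`
#'   matched to each reference mode), `signs` (+1/-1 per mode),
#'   `match_scores` (absolute correlations in \[0, 1\]) and `flagged`.
#' @export
match_modes <- function(reference, other, flag_threshold = 0.5) {
  if (reference$k != other$k)
    stop("solutions have different k: ", reference$k, " vs ", other$k)
  if (!identical(reference$dn_labels, other$dn_labels) ||
      !identical(reference$hc_labels, other$hc_labels))
    stop("solutions were fitted on different subregion column sets")
  k <- reference$k
  Wref <- rbind(reference$v_weights, reference$u_weights)
  Woth <- rbind(other$v_weights, other$u_weights)
  S <- stats::cor(Wref, Woth)           # k x k signed correlations
  perm <- solve_assignment(-abs(S))
  signed <- S[cbind(seq_len(k), perm)]
  structure(list(permutation = perm,
                 signs = ifelse(signed < 0, -1, 1),
                 match_scores = abs(signed),
                 flagged = abs(signed) < flag_threshold),
            class = "mode_match")
}

#' @export
print.mode_match <- function(x, ...) {
  cat(sprintf("mode_match: k = %d, %d sign flip(s), %d flagged (< threshold)\n",
              length(x$permutation), sum(x$signs < 0), sum(x$flagged)))
  cat("scores:", paste(sprintf("%.2f", x$match_scores), collapse = " "), "\n")
  invisible(x)
}

#' Reorder and sign-flip a solution to align with its reference
#'
#' Applies a [match_modes()] result so mode `l` of the returned solution
#' corresponds (in order and sign) to mode `l` of the reference; variates and
#' canonical correlations are transformed consistently.
#'
#' @param other The `cca_solution` the match was computed for.
#' @param match A `mode_match` from `match_modes(reference, other)`.
#' @return The aligned `cca_solution`.
#' @export
apply_match <- function(other, match) {
  k <- other$k
  if (length(match$permutation) != k)
    stop("match and solution disagree on k")
  pm <- match$permutation; sg <- match$signs
  flip <- function(m) sweep(m[, pm, drop = FALSE], 2, sg, `*`)
  out <- other
  out$v_weights <- flip(other$v_weights)
  out$u_weights <- flip(other$u_weights)
  out$dn_variates <- flip(other$dn_variates)
  out$hc_variates <- flip(other$hc_variates)
  out$cor <- other$cor[pm]
  labs <- paste0("mode", seq_len(k))
  colnames(out$v_weights) <- colnames(out$u_weights) <- labs
  colnames(out$dn_variates) <- colnames(out$hc_variates) <- labs
  out
}

#' Serialize a mode match to JSON
#'
#' @param match A `mode_match`.
#' @param path JSON file path.
#' @return `write_mode_match` returns `path` invisibly; `read_mode_match` the
#'   match object.
#' @export
write_mode_match <- function(match, path) {
  jsonlite::write_json(unclass(match), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_mode_match
#' @export
read_mode_match <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(permutation = as.integer(x$permutation), signs = x$signs,
                 match_scores = x$match_scores, flagged = x$flagged),
            class = "mode_match")
}
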