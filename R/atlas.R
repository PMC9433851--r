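#' Hippocampal subfield atlas table
#'
#' Returns the default anatomy table for the 38 hippocampal subfield volumes
#' (19 per hemisphere), mirroring the FreeSurfer hippocampal sub-segmentation
#' naming: CA1, CA2/3, CA4, the granule-cell / molecular layer of the dentate
#' gyrus (DG), the molecular layer (ML), subiculum (Sub), presubiculum (PrS),
#' parasubiculum (Para), HATA, fimbria, hippocampal fissure and tail, with the
#' larger subfields split into head and body portions.
#'
#' Structures that the segmentation does not split are assigned to the portion
#' in which they anatomically sit (Para and HATA to the head; fimbria and tail
#' to the body); the fissure, a CSF gap rather than tissue, carries no
#' head/body label.
#'
#' @return A data.frame with columns `subregion`, `structure` (always `"HC"`),
#'   `hemisphere` (`"L"`/`"R"`), `category` (one of the 12 subfield groups) and
#'   `part` (`"head"`, `"body"` or `NA`).
#' @export
#' @examples
#' table(hc_atlas()$category)
hc_atlas <- function() {
  per_hemi <- data.frame(
    category = c("CA1", "CA1", "CA2/3", "CA2/3", "CA4", "CA4", "DG", "DG",
                 "ML", "ML", "Sub", "Sub", "PrS", "PrS", "Para", "HATA",
                 "Fimbria", "Fissure", "Tail"),
    part = c("head", "body", "head", "body", "head", "body", "head", "body",
             "head", "body", "head", "body", "head", "body", "head", "head",
             "body", NA, "body"),
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, lapply(c("L", "R"), function(h) {
    d <- per_hemi
    d$hemisphere <- h
    d
  }))
  slug <- gsub("[^A-Za-z0-9]", "", out$category)
  out$subregion <- paste0(out$hemisphere, "_", slug,
                          ifelse(is.na(out$part), "", paste0("_", out$part)))
  out$structure <- "HC"
  rownames(out) <- NULL
  out[, c("subregion", "structure", "hemisphere", "category", "part")]
}

#' Default-network parcel atlas table
#'
#' Returns the default anatomy table for the 91 default-network (DN) parcels,
#' labeled by hemisphere and grouped into the four lobe categories used for
#' anatomical tallies: temporal, prefrontal, parietal and posterior cingulate.
#' The parcel-to-category mapping is a reconstruction of a Schaefer-style
#' 7-network parcellation restricted to the DN (the source parcellation does
#' not publish a four-category grouping); counts per category are 23 temporal,
#' 30 prefrontal, 22 parietal and 16 posterior cingulate.
#'
#' @return A data.frame with columns `subregion`, `structure` (always `"DN"`),
#'   `hemisphere` and `category`; `part` is `NA` (head/body does not apply to
#'   neocortical parcels).
#' @export
#' @examples
#' table(dn_atlas()$category, dn_atlas()$hemisphere)
dn_atlas <- function() {
  counts <- list(
    Temporal = c(L = 12, R = 11),
    Prefrontal = c(L = 15, R = 15),
    Parietal = c(L = 11, R = 11),
    `Posterior cingulate` = c(L = 8, R = 8)
  )
  rows <- lapply(names(counts), function(cat) {
    do.call(rbind, lapply(c("L", "R"), function(h) {
      n <- counts[[cat]][[h]]
      slug <- gsub("[^A-Za-z0-9]", "", cat)
      data.frame(
        subregion = paste0(h, "_", slug, "_", seq_len(n)),
        structure = "DN", hemisphere = h, category = cat,
        part = NA_character_, stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
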