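## IGF2 promoter usage (adult P0-P1 vs fetal P2/P3/P4) from splice-junction
## depths.

#' Assemble junction depth summaries for one sample
#'
#' @param categoryDepths Named numeric over the four promoter categories
#'   ([PROMOTER_CATEGORIES]): the maximum junction depth per category.
#' @param universalDepth Depth at "universal" junctions, those shared by all
#'   transcripts; required positive for normalization.
#' @return A list of class `"junctionCounts"`.
#' @export
junctionCounts <- function(categoryDepths, universalDepth) {
  if (!all(PROMOTER_CATEGORIES %in% names(categoryDepths)))
    stop("categoryDepths must name all of: ",
         paste(PROMOTER_CATEGORIES, collapse = ", "))
  categoryDepths <- categoryDepths[PROMOTER_CATEGORIES]
  if (any(categoryDepths < 0) || universalDepth < 0)
    stop("junction depths must be non-negative")
  structure(list(categoryDepths = categoryDepths,
                 universalDepth = universalDepth),
            class = "junctionCounts")
}

#' Normalize category junction depths by the universal-junction depth
#'
#' @param jc A [junctionCounts()] object.
#' @return Named numeric of normalized depths; these are comparable across
#'   samples as absolute promoter activity.
#' @export
normalizeJunctions <- function(jc) {
  stopifnot(inherits(jc, "junctionCounts"))
  if (jc$universalDepth == 0)
    stop("universal junction depth is zero; cannot normalize")
  jc$categoryDepths / jc$universalDepth
}

#' Promoter-usage proportions and the fetal fraction
#'
#' Normalized category depths are rescaled to proportions summing to 1; the
#' fetal fraction is the P2+P3+P4 share. Within one sample the universal
#' normalization cancels in the proportion, but the normalized values are
#' also retained for cross-sample comparison.
#'
#' @param jc A [junctionCounts()] object.
#' @param sampleId Optional sample label.
#' @return A [PromoterUsage-class]; when no category carries signal the
#'   proportions are NA (usage absent).
#' @examples
#' jc <- junctionCounts(c("P0-P1" = 10, P2 = 30, P3 = 40, P4 = 20), 100)
#' usageProportions(promoterUsage(jc))
#' @export
promoterUsage <- function(jc, sampleId = NA_character_) {
  norm <- normalizeJunctions(jc)
  total <- sum(norm)
  if (total == 0) {
    props <- stats::setNames(rep(NA_real_, 4L), PROMOTER_CATEGORIES)
    fetal <- NA_real_
  } else {
    props <- norm / total
    fetal <- sum(props[c("P2", "P3", "P4")])
  }
  new("PromoterUsage", sampleId = as.character(sampleId), normalized = norm,
      proportions = props, fetalFraction = fetal)
}

#' Summarise a junction depth table into per-sample category maxima
#'
#' Junction-to-category assignment comes from a user-supplied map, since the
#' categories are defined by transcript structure rather than fixed
#' coordinates. Per sample and category the maximum junction depth is taken;
#' the universal depth is the maximum over junctions mapped to
#' `"universal"`.
#'
#' @param junctions A `data.frame` with columns `sample_id`, `junction_id`,
#'   `depth`.
#' @param categoryMap A `data.frame` with columns `junction_id`, `category`
#'   (one of [PROMOTER_CATEGORIES] or `"universal"`).
#' @return A named list of [junctionCounts()] objects, one per sample.
#' @export
summarizeJunctionTable <- function(junctions, categoryMap) {
  stopifnot(all(c("sample_id", "junction_id", "depth") %in% names(junctions)),
            all(c("junction_id", "category") %in% names(categoryMap)))
  ok <- categoryMap$category %in% c(PROMOTER_CATEGORIES, "universal")
  if (!all(ok))
    stop("unknown categories in map: ",
         paste(unique(categoryMap$category[!ok]), collapse = ", "))
  junctions$category <- categoryMap$category[
    match(junctions$junction_id, categoryMap$junction_id)]
  unmapped <- is.na(junctions$category)
  if (any(unmapped)) {
    message(sprintf("ignoring %d junction rows absent from the category map",
                    sum(unmapped)))
    junctions <- junctions[!unmapped, , drop = FALSE]
  }
  lapply(split(junctions, junctions$sample_id), function(d) {
    maxDepth <- function(cat) {
      v <- d$depth[d$category == cat]
      if (length(v)) max(v) else 0
    }
    junctionCounts(
      stats::setNames(vapply(PROMOTER_CATEGORIES, maxDepth, numeric(1)),
                      PROMOTER_CATEGORIES),
      universalDepth = maxDepth("universal"))
  })
}
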