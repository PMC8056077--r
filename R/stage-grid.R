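#' Developmental stage grid for the embryo expression atlas
#'
#' The expression data are sampled at seven morphologically defined embryo
#' stages. Each stage is assigned a time in days after fertilization (DAF);
#' the default mapping places the mature stage at 18 DAF so that the full
#' simulation window (0--21 DAF) brackets the sampled stages.
#'
#' @param stage_names Character vector of 7 stage labels, in developmental
#'   order.
#' @param stage_daf Numeric vector of 7 times (DAF) assigned to the stages.
#'   Must be strictly increasing, start at 0 and end at or before 21.
#' @return A tibble with columns `stage` (ordered factor), `time_daf` and
#'   `time_hr`.
#' @examples
#' stage_grid()
#' @export
stage_grid <- function(stage_names = c("zygote", "octant", "globular", "heart",
                                       "torpedo", "bent", "mature"),
                       stage_daf = c(0, 1, 2, 4, 6, 10, 18)) {
  if (length(stage_names) != 7L || length(stage_daf) != 7L) {
    stop("a stage grid has exactly 7 stages", call. = FALSE)
  }
  if (anyDuplicated(stage_names)) {
    stop("stage names must be unique", call. = FALSE)
  }
  if (any(diff(stage_daf) <= 0)) {
    stop("stage times must be strictly increasing", call. = FALSE)
  }
  if (stage_daf[1] != 0) {
    stop("the first stage is fixed at 0 DAF", call. = FALSE)
  }
  if (stage_daf[7] > 21) {
    stop("the last stage must lie at or before 21 DAF", call. = FALSE)
  }
  tibble::tibble(
    stage = factor(stage_names, levels = stage_names, ordered = TRUE),
    time_daf = as.numeric(stage_daf),
    time_hr = as.numeric(stage_daf) * 24
  )
}

#' @keywords internal
assert_stage_grid <- function(grid) {
  stopifnot(is.data.frame(grid), all(c("stage", "time_daf", "time_hr") %in% names(grid)))
  invisible(grid)
}
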