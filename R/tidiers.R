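#' Tidy and glance methods for scoring results
#'
#' `tidy()` returns the per-slice measurement table of a result;
#' `glance()` returns a one-row tibble of its stack- or speck-level totals.
#'
#' @param x a scoring result object.
#' @param ... unused.
#' @return A tibble.
#' @name calscore-tidiers
NULL

#' @rdname calscore-tidiers
#' @export
tidy.stack_score <- function(x, ...) x$per_slice

#' @rdname calscore-tidiers
#' @export
glance.stack_score <- function(x, ...) {
  tibble(
    axis_label = x$axis_label,
    modality = x$modality,
    total_score = x$total_score,
    total_volume_index = x$total_volume_index,
    total_volume_mm3 = x$total_volume_mm3,
    n_slices = nrow(x$per_slice)
  )
}

#' @rdname calscore-tidiers
#' @export
tidy.us_calcium_result <- function(x, ...) {
  bind_rows(
    mutate(x$short_axis$per_slice, axis = "short", .before = 1),
    mutate(x$long_axis$per_slice, axis = "long", .before = 1)
  )
}

#' @rdname calscore-tidiers
#' @export
glance.us_calcium_result <- function(x, ...) {
  tibble(
    us_calcium_score = x$us_calcium_score,
    us_calcium_volume = x$us_calcium_volume,
    short_axis_score = x$short_axis$total_score,
    long_axis_score = x$long_axis$total_score
  )
}

#' @rdname calscore-tidiers
#' @export
tidy.ct_calcium_result <- function(x, ...) x$per_slice

#' @rdname calscore-tidiers
#' @export
glance.ct_calcium_result <- function(x, ...) {
  tibble(
    ct_calcium_score = x$ct_calcium_score,
    ct_calcium_volume = x$ct_calcium_volume,
    total_volume_mm3 = x$total_volume_mm3,
    hu_threshold = x$hu_threshold,
    pv_threshold = x$pv_threshold
  )
}

#' @rdname calscore-tidiers
#' @export
tidy.cib_result <- function(x, ...) {
  bind_rows(
    mutate(x$short_axis, axis = "short", .before = 1),
    mutate(x$long_axis, axis = "long", .before = 1)
  )
}

#' @rdname calscore-tidiers
#' @export
glance.cib_result <- function(x, ...) {
  tibble(
    cib_calcium_score = x$cib_calcium_score,
    short_axis_sum = x$short_axis_sum,
    long_axis_sum = x$long_axis_sum
  )
}

#' @rdname calscore-tidiers
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname calscore-tidiers
#' @export
glance.roc_result <- function(x, ...) {
  tibble(
    auc = x$auc,
    optimal_cutoff = x$optimal_cutoff,
    sensitivity = x$sens_at_cutoff,
    specificity = x$spec_at_cutoff,
    n_pos = x$n_pos,
    n_neg = x$n_neg
  )
}
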