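#' Risky-choice proportions stratified by previous outcome
#'
#' On mixed 5-vs-25-cent offers, the proportion of trials on which the
#' 25-cent option was chosen, computed separately for trials following a
#' gain and following a loss. Equal-offer trials (5/5, 25/25) and trials
#' whose previous outcome is `none` (the first trial of a session, or of a
#' block when `reset_at_block`) never enter numerator or denominator. With
#' an empty denominator the proportion is `NA` and `defined` is `FALSE`,
#' not an error.
#'
#' @param trials trial table with `subject_id`, `offer_left`,
#'   `offer_right`, `chosen_value`, `prev_outcome` (regenerated from
#'   `outcome`/`block` order when absent).
#' @param reset_at_block treat the first trial of each block as having no
#'   previous outcome.
#' @return data.frame per subject: `risky_after_gain`, `risky_after_loss`,
#'   `n_mixed_after_gain`, `n_mixed_after_loss`, `defined`.
#' @export
risky_choice_proportion <- function(trials, reset_at_block = FALSE) {
  if (!"prev_outcome" %in% names(trials)) {
    trials <- trials[order(trials$subject_id, trials$trial), ]
    trials$prev_outcome <- stats::ave(
      trials$outcome, trials$subject_id,
      FUN = function(o) c("none", o[-length(o)]))
  }
  if (reset_at_block && "block" %in% names(trials)) {
    first <- stats::ave(trials$block, trials$subject_id,
                        FUN = function(b) c(TRUE, diff(b) != 0)) == 1
    trials$prev_outcome[first] <- "none"
  }
  mixed <- trials$offer_left != trials$offer_right
  out <- lapply(split(trials, trials$subject_id), function(tt) {
    mm <- tt[tt$offer_left != tt$offer_right &
               tt$prev_outcome %in% c("gain", "loss"), , drop = FALSE]
    cnt <- function(pv) sum(mm$prev_outcome == pv)
    prop <- function(pv) {
      den <- cnt(pv)
      if (den == 0) NA_real_
      else sum(mm$prev_outcome == pv & mm$chosen_value == 25) / den
    }
    data.frame(subject_id = tt$subject_id[1],
               risky_after_gain = prop("gain"),
               risky_after_loss = prop("loss"),
               n_mixed_after_gain = cnt("gain"),
               n_mixed_after_loss = cnt("loss"),
               defined = cnt("gain") > 0 && cnt("loss") > 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
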