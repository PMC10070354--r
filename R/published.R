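#' Published multinomial-logit coefficients and relative risk ratios
#'
#' The per-condition multinomial-logit slopes and the corresponding relative
#' risk ratios reported by the emotion-regulation study of global signal
#' topography in depression that this package models. Rows appear in the
#' order the source printed them. These values serve two purposes: as
#' reference points for consistency checks (exponentiating each coefficient
#' must reproduce its printed RRR) and as the default ground-truth slopes of
#' the behavioural simulator ([default_behavior_coefs()]).
#'
#' The `group` term is the past-depressive-episode indicator; `contrast`
#' names the response category compared against the condition's reference
#' (mild for negative stimuli, weak for neutral). The neutral-condition
#' strong contrast was reported as an RRR only; its coefficient column is
#' `NA` there.
#'
#' @return A tibble with columns `condition`, `contrast`, `term`,
#'   `coefficient`, `rrr`.
#' @export
published_mlr_coefficients <- function() {
  tibble::tribble(
    ~condition, ~contrast, ~term, ~coefficient, ~rrr,
    "negative_attend", "weak_vs_mild", "interoceptive", 8.397, 4434.731,
    "negative_attend", "weak_vs_mild", "mental", -2.851, 0.058,
    "negative_attend", "moderate_vs_mild", "interoceptive", 2.032, 7.627,
    "negative_attend", "moderate_vs_mild", "exteroceptive", -1.418, 0.242,
    "negative_attend", "moderate_vs_mild", "group", 1.043, 2.839,
    "negative_attend", "strong_vs_mild", "group", 1.683, 5.382,
    "negative_reappraise", "weak_vs_mild", "interoceptive", 4.378, 79.652,
    "negative_reappraise", "weak_vs_mild", "exteroceptive", 2.209, 9.103,
    "negative_reappraise", "weak_vs_mild", "group", -1.396, 0.248,
    "negative_reappraise", "moderate_vs_mild", "exteroceptive", -1.037, 0.354,
    "negative_reappraise", "moderate_vs_mild", "group", 0.78, 2.181,
    "negative_reappraise", "strong_vs_mild", "interoceptive", 2.778, 16.086,
    "negative_reappraise", "strong_vs_mild", "exteroceptive", -4.432, 0.012,
    "negative_reappraise", "strong_vs_mild", "group", 1.46, 4.307,
    "neutral_attend", "mild_vs_weak", "exteroceptive", -2.849, 0.058,
    "neutral_attend", "mild_vs_weak", "mental", 1.675, 5.338,
    "neutral_attend", "mild_vs_weak", "group", 0.58, 1.724,
    "neutral_attend", "moderate_vs_weak", "exteroceptive", -2.02, 0.133,
    "neutral_attend", "moderate_vs_weak", "group", 1.721, 5.589,
    "neutral_attend", "strong_vs_weak", "group", NA_real_, 8.145
  )
}
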