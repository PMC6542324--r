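# ggplot2 views of the simulator's result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_bar geom_line geom_point
#'   facet_wrap labs theme_minimal scale_fill_manual
NULL

status_palette <- c(
  VALID = "#2c7fb8",
  BRANCH_RESOLVED_LEGAL = "#7fcdbb",
  TAMPERED_REJECTED = "#d7301f",
  BRANCH_REJECTED_ILLEGAL = "#fc8d59",
  BRANCH_UNRESOLVED = "#756bb1",
  UNVERIFIABLE = "#bdbdbd"
)

#' Plot an audit report
#'
#' Bar chart of the per-payload legality classification, one panel per
#' account.
#'
#' @param object An `audit_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot audit_report
#' @export
autoplot.audit_report <- function(object, ...) {
  cl <- object$classification
  ggplot(cl, aes(x = .data$status, fill = .data$status)) +
    geom_bar() +
    facet_wrap(~account_id) +
    scale_fill_manual(values = status_palette, drop = TRUE) +
    labs(
      x = NULL, y = "committed payloads",
      title = "Audit classification of committed records",
      subtitle = if (object$offline_check_required) {
        "unresolved branch: offline device check required"
      } else {
        NULL
      }
    ) +
    theme_minimal() +
    ggplot2::theme(legend.position = "none", axis.text.x = ggplot2::element_text(
      angle = 30, hjust = 1
    ))
}

#' Plot a simulated trial
#'
#' Questionnaire-score trajectories of the synthetic cohort over study
#' days.
#'
#' @param object An `mhealth_trial`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mhealth_trial
#' @export
autoplot.mhealth_trial <- function(object, ...) {
  long <- object$records %>%
    select("account_id", "seq", "ais_total", "ess_total", "qids_total") %>%
    tidyr::pivot_longer(
      c("ais_total", "ess_total", "qids_total"),
      names_to = "scale", values_to = "score"
    )
  ggplot(long, aes(x = .data$seq, y = .data$score, colour = .data$account_id)) +
    geom_line(alpha = 0.7) +
    geom_point(size = 0.8) +
    facet_wrap(~scale, scales = "free_y") +
    labs(
      x = "record index", y = "total score", colour = "account",
      title = "Synthetic patient-reported outcomes"
    ) +
    theme_minimal()
}
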