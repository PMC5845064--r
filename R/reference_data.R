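# Reference label distribution shipped with the package.

#' Reference OSATS rating distribution
#'
#' Distribution of rounded-average OSATS scores (1-4; no trial merited a 5)
#' by training level for the 63-trial intracorporeal-suturing cohort the
#' rating pipeline was designed around: 12 medical-student, 41 resident and
#' 10 fellow trials. Used to benchmark the constant (median) baseline and
#' as the target composition for the synthetic cohort.
#'
#' @return data.frame with columns `level`, `score`, `count`.
#' @export
reference_rating_distribution <- function() {
  utils::read.csv(system.file("extdata", "rating_distribution.csv",
                              package = "lapskill"),
                  stringsAsFactors = FALSE)
}

#' Expand the reference distribution into per-trial labels
#'
#' @return data.frame with one row per trial: `level`, `rounded_avg`.
#' @export
reference_rating_labels <- function() {
  d <- reference_rating_distribution()
  d <- d[rep(seq_len(nrow(d)), d$count), c("level", "score")]
  names(d) <- c("level", "rounded_avg")
  rownames(d) <- NULL
  d
}
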