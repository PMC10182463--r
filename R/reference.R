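#' Reference condition-level summaries of the two-phase IPV severity study
#'
#' Condition-level summary statistics (sample sizes, correlations, means and
#' SDs of severity ratings) of the two-phase intimate partner violence (IPV)
#' severity-rating study that this package's synthetic generator emulates.
#' In phase 1 (P1) participants described self-experienced violent events
#' with five keywords and rated their severity on a 0--10 scale; in phase 2
#' (P2) a second set of raters read those descriptions and re-rated them.
#' MP2 denotes the computational model's out-of-fold predicted severity for
#' the P2 responses.
#'
#' These values anchor the defaults of [study_config()] (latent means/SDs and
#' calibration shifts) and provide the arithmetic check that
#' [calibration_bias()] reproduces the published bias entries from the
#' printed means.
#'
#' @return A data frame with one row per condition (`both`, `psychological`,
#'   `physical`) and columns `n_points`, `r_p1_p2`, `r_p1_mp1`, `r_p1_mp2`,
#'   `mean_p1`, `sd_p1`, `mean_p2`, `sd_p2`, `mean_mp2`, `sd_mp2`.
#' @examples
#' ref <- reference_summary()
#' # human calibration bias for psychological violence: P2 mean minus P1 mean
#' calibration_bias(ref$mean_p1[2], ref$mean_p2[2])
#' @export
reference_summary <- function() {
  data.frame(
    condition = c("both", "psychological", "physical"),
    n_points  = c(2720L, 1360L, 1360L),
    r_p1_p2   = c(0.36, 0.24, 0.47),
    r_p1_mp1  = c(0.48, 0.42, 0.54),
    r_p1_mp2  = c(0.58, 0.59, 0.56),
    mean_p1   = c(6.52, 6.46, 6.59),
    sd_p1     = c(1.75, 1.69, 1.81),
    mean_p2   = c(6.69, 5.85, 7.54),
    sd_p2     = c(2.84, 2.80, 2.62),
    mean_mp2  = c(6.88, 6.91, 6.85),
    sd_mp2    = c(2.67, 2.31, 2.99),
    stringsAsFactors = FALSE
  )
}
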