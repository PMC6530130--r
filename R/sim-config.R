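#' Simulation configuration for the two-cohort blood study emulator
#'
#' Bundles every knob of the synthetic-data generator. Defaults are a scaled
#' (~1/4 size) version of a two-cohort whole-blood ALS case-control design:
#' cohort C1 (platform V3) with 60 ALS / 120 CTL, cohort C2 (platform V4)
#' with 40 ALS / 35 CTL / 20 MIM (mimic) samples, 2000 genes of which 1800
#' are shared between the platforms.
#'
#' Group effects are realized two ways, mirroring how disease reshapes whole
#' blood: (i) cell-type composition shifts (ALS raises the neutrophil
#' Dirichlet mean 1.5x and lowers the erythroid mean 0.67x) and (ii) direct
#' differential expression planted on `n_deg` genes at `deg_lfc` log2 units.
#' Technical structure: an additive per-gene batch shift on the second
#' index-contiguous block of each cohort, a per-gene platform offset on C2,
#' a sex effect on a gene subset, and Gaussian noise. Detection p-values are
#' generated as a decreasing sigmoid of intensity plus uniform noise and are
#' inverted (p -> 1 - p) for a `detect_flip_frac` subset of samples.
#'
#' @param n1_als,n1_ctl cohort C1 group sizes.
#' @param n2_als,n2_ctl,n2_mim cohort C2 group sizes (MIM only exists in C2).
#' @param n_genes,n_shared total gene universe and size of the shared panel;
#'   the remaining genes are split evenly into platform-private panels.
#' @param base_props named baseline cell-type proportions (sum to 1).
#' @param prop_multipliers named list per group of named multipliers applied
#'   to the Dirichlet mean of that group.
#' @param dirichlet_conc Dirichlet concentration (larger = less variation).
#' @param n_deg,deg_lfc number of planted DEGs and their log2 effect size
#'   (half planted up, half down).
#' @param n_sex_genes,sex_effect genes carrying a male-additive shift.
#' @param batch_shift_sd per-gene SD of the additive shift applied to the
#'   second sample-index block of each cohort (log2 units).
#' @param batch_frac fraction of each cohort's samples in the first block.
#' @param platform_offset_sd per-gene SD of the C2 platform offset.
#' @param noise_sd residual log2 Gaussian noise.
#' @param detect_flip_frac fraction of samples whose detection p-values are
#'   stored as 1 - p.
#' @param detect_slope,detect_mid_q,detect_noise sigmoid slope, per-sample
#'   intensity quantile placing the sigmoid midpoint, and uniform noise
#'   half-width (logit units) of the detection p model.
#' @param n_surv_genes,surv_loghr planted survival genes and |log HR| per SD
#'   of expression (signs alternate).
#' @param weibull_shape,median_surv Weibull shape and baseline median
#'   survival (years) of the event-time model.
#' @param cens_frac target fraction of censored ALS patients.
#' @param seed integer seed recorded in the output.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n1_als = 60, n1_ctl = 120,
                       n2_als = 40, n2_ctl = 35, n2_mim = 20,
                       n_genes = 2000, n_shared = 1800,
                       base_props = c(NP = 0.55, MC = 0.08, DC = 0.01,
                                      MP = 0.01, PL = 0.08, RBC = 0.06,
                                      ES = 0.02, CD4 = 0.08, CD8 = 0.05,
                                      GDT = 0.01, B = 0.03, NK = 0.02),
                       prop_multipliers = list(ALS = c(NP = 1.5, RBC = 0.67)),
                       dirichlet_conc = 80,
                       n_deg = 50, deg_lfc = 0.5,
                       n_sex_genes = 25, sex_effect = 0.5,
                       batch_shift_sd = 0.4, batch_frac = 0.6,
                       platform_offset_sd = 0.25,
                       noise_sd = 0.3,
                       detect_flip_frac = 0.30,
                       detect_slope = 3, detect_mid_q = 0.20,
                       detect_noise = 0.5,
                       n_surv_genes = 5, surv_loghr = 0.5,
                       weibull_shape = 1.5, median_surv = 2.5,
                       cens_frac = 0.30,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    all(vapply(cfg[c("n1_als", "n1_ctl", "n2_als", "n2_ctl")], function(x)
      x > 0, logical(1))),
    n2_mim >= 0,
    n_shared <= n_genes,
    (n_genes - n_shared) %% 2 == 0,
    abs(sum(base_props) - 1) < 1e-8,
    detect_flip_frac >= 0, detect_flip_frac <= 1,
    batch_frac > 0, batch_frac < 1,
    cens_frac >= 0, cens_frac < 1,
    n_deg >= 0, n_surv_genes >= 0
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> C1:", x$n1_als, "ALS /", x$n1_ctl, "CTL; C2:",
      x$n2_als, "ALS /", x$n2_ctl, "CTL /", x$n2_mim, "MIM;",
      x$n_genes, "genes (", x$n_shared, "shared ); seed", x$seed, "\n")
  invisible(x)
}
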