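# Synthetic cohort generation: marker profiles built as the classifier's
# inverse image, piecewise-exponential survival, seeded end to end.

#' Closed-form RMST of a piecewise-exponential survival curve
#'
#' @param rates Hazard rates per month, one per segment (zero allowed).
#' @param breaks Segment start times (first must be 0), same length.
#' @param horizon Integration horizon in months.
#' @return Restricted mean survival time in months.
#' @export
piecewise_exp_rmst <- function(rates, breaks = 0, horizon = 60) {
  stopifnot(length(rates) == length(breaks), breaks[1] == 0,
            !is.unsorted(breaks), all(rates >= 0))
  ends <- c(breaks[-1], Inf)
  total <- 0
  cumhaz <- 0
  for (j in seq_along(rates)) {
    a <- breaks[j]
    b <- min(ends[j], horizon)
    if (b <= a) break
    s_a <- exp(-cumhaz)
    if (rates[j] == 0) {
      total <- total + s_a * (b - a)
    } else {
      total <- total + s_a * (1 - exp(-rates[j] * (b - a))) / rates[j]
      cumhaz <- cumhaz + rates[j] * (b - a)
    }
  }
  total
}

# Inverse-transform draws from a piecewise-exponential hazard; Inf when the
# drawn cumulative hazard is never reached (e.g. trailing zero rates).
rpiecewise_exp <- function(n, rates, breaks = 0) {
  stopifnot(length(rates) == length(breaks), breaks[1] == 0, all(rates >= 0))
  if (any(rates < 0)) abort("nonpositive rates", class = "endomol_sim_error")
  ends <- c(breaks[-1], Inf)
  u <- runif(n)
  target <- -log(u)
  out <- rep(Inf, n)
  cumhaz <- 0
  for (j in seq_along(rates)) {
    seg <- ends[j] - breaks[j]
    add <- if (is.finite(seg)) rates[j] * seg else
      if (rates[j] > 0) Inf else 0
    hit <- is.infinite(out) & rates[j] > 0 & target <= cumhaz + add
    out[hit] <- breaks[j] + (target[hit] - cumhaz) / rates[j]
    cumhaz <- cumhaz + if (is.finite(add)) add else 0
    if (is.infinite(add)) break
  }
  out
}

#' Calibrate piecewise-exponential rates to a target RMST
#'
#' Scales a relative hazard profile so its closed-form restricted mean
#' survival time equals the target, by root-finding on the (monotone) scale
#' factor. `target_rmst == horizon` returns zero hazard exactly.
#'
#' @param target_rmst Target RMST in months, in `(0, horizon]`.
#' @param horizon Horizon in months.
#' @param breaks Segment start times (first 0).
#' @param weights Nonnegative relative segment hazards (some must act before
#'   `horizon`).
#' @return Numeric rate vector with
#'   `piecewise_exp_rmst(rates, breaks, horizon)` within 1e-6 of the target.
#' @export
calibrate_rates <- function(target_rmst, horizon = 60, breaks = 0,
                            weights = rep(1, length(breaks))) {
  stopifnot(length(weights) == length(breaks))
  if (target_rmst > horizon) {
    abort("target_rmst exceeds horizon", class = "endomol_sim_error")
  }
  if (target_rmst <= 0) {
    abort("target_rmst must be positive", class = "endomol_sim_error")
  }
  if (target_rmst == horizon) return(numeric(length(breaks)))
  f <- function(logc) {
    piecewise_exp_rmst(exp(logc) * weights, breaks, horizon) - target_rmst
  }
  root <- uniroot(f, interval = c(-25, 10), extendInt = "downX",
                  tol = 1e-12)$root
  exp(root) * weights
}

#' Specification for a synthetic cohort
#'
#' The defaults emulate the study conditions: 186 recruited patients, a 25.8%
#' DNA quality-control failure rate, subgroup probabilities
#' (NSMP 0.529, MMR-d 0.282, p53-abn 0.138, POLE-mut 0.051), per-subgroup
#' stage/histology/invasion/LVSI/nodal distributions matching the published
#' cohort margins, and progression-free survival hazards calibrated so the
#' 5-year RMST per subgroup equals the published adjusted estimates
#' (NSMP 53.2, MMR-d 51.1, p53-abn 29.5 months; POLE-mut event-free before
#' month 60 by construction). Overall survival couples to progression as
#' progression time plus an exponential residual. Administrative censoring is
#' uniform on 60-95 months, so event-free patients always have at least 60
#' months of follow-up.
#'
#' @param n_recruited Number recruited (before DNA QC exclusion).
#' @param qc_failure_rate Probability a sample fails GAPDH amplification.
#' @param subgroup_probs Named probabilities over the four subgroups (sum 1).
#' @param pfs_rmst Named 5-year PFS RMST calibration targets (months) for the
#'   three subgroups with events; POLE-mut is event-free (zero hazard).
#' @param os_residual_mean Named mean (months) of the exponential
#'   progression-to-death residual.
#' @param censor_window Administrative follow-up window `c(min, max)` months.
#' @param seed Integer seed driving all randomness.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_recruited = 186,
                        qc_failure_rate = 0.258,
                        subgroup_probs = c(MMR_d = 0.282, POLE_mut = 0.051,
                                           p53_abn = 0.138, NSMP = 0.529),
                        pfs_rmst = c(MMR_d = 51.1, p53_abn = 29.5,
                                     NSMP = 53.2),
                        os_residual_mean = c(MMR_d = 18, POLE_mut = 18,
                                             p53_abn = 9, NSMP = 18),
                        censor_window = c(60, 95),
                        seed = 1L) {
  if (abs(sum(subgroup_probs) - 1) > 1e-8 || any(subgroup_probs < 0)) {
    abort("subgroup_probs must be nonnegative and sum to 1",
          class = "endomol_sim_error")
  }
  stopifnot(setequal(names(subgroup_probs), SUBGROUPS),
            length(censor_window) == 2, censor_window[1] >= 60 - 1e-9,
            censor_window[2] >= censor_window[1])
  survival_params <- list(
    MMR_d = list(breaks = 0, rates = calibrate_rates(pfs_rmst[["MMR_d"]])),
    p53_abn = list(breaks = 0, rates = calibrate_rates(pfs_rmst[["p53_abn"]])),
    NSMP = list(breaks = 0, rates = calibrate_rates(pfs_rmst[["NSMP"]])),
    # event-free by construction, matching the observed subgroup
    POLE_mut = list(breaks = 0, rates = 0)
  )
  structure(
    list(n_recruited = n_recruited, qc_failure_rate = qc_failure_rate,
         subgroup_probs = subgroup_probs[SUBGROUPS],
         conditional = default_conditionals(),
         survival_params = survival_params,
         os_residual_mean = os_residual_mean,
         censor_window = censor_window, seed = as.integer(seed)),
    class = "cohort_spec")
}

# Per-subgroup conditional distributions taken from the published cohort
# margins (early-stage fraction, histology, invasion, LVSI, nodes, age).
default_conditionals <- function() {
  list(
    MMR_d = list(early = 25 / 39, histology = c(25, 12, 2) / 39,
                 invasion = c(20, 13, 6) / 39, lvsi_yes = 24 / 39,
                 nodes = c(24, 7, 8) / 39, age_mean = 58.5, age_sd = 10),
    POLE_mut = list(early = 5 / 7, histology = c(4, 3, 0) / 7,
                    invasion = c(3, 4, 0) / 7, lvsi_yes = 3 / 7,
                    nodes = c(5, 1, 1) / 7, age_mean = 57.3, age_sd = 7),
    p53_abn = list(early = 5 / 19, histology = c(0, 7, 12) / 19,
                   invasion = c(9, 2, 8) / 19, lvsi_yes = 12 / 19,
                   nodes = c(5, 6, 8) / 19, age_mean = 60.8, age_sd = 12),
    NSMP = list(early = 45 / 73, histology = c(52, 17, 4) / 73,
                invasion = c(40, 27, 6) / 73, lvsi_yes = 39 / 73,
                nodes = c(43, 16, 14) / 73, age_mean = 55.5, age_sd = 11)
  )
}

# POLE hotspot protein changes with their exonuclease-domain exons.
HOTSPOT_EXONS <- c(P286R = 9L, S297F = 9L, V411L = 13L, A456P = 14L,
                   S459F = 14L)

#' Generate survival outcomes for given subgroups
#'
#' Progression times are drawn by inverse transform on the subgroup's
#' piecewise-exponential cumulative hazard; death time is progression time
#' plus an exponential residual (so progression-free time never exceeds
#' overall time); administrative censoring is uniform over the follow-up
#' window.
#'
#' @param subgroup Character vector of subgroups.
#' @param survival_params Named list of `list(breaks, rates)` per subgroup.
#' @param os_residual_mean Named means of the progression-to-death residual.
#' @param censor_window `c(min, max)` follow-up months.
#' @param seed Optional seed; omit to draw from the current RNG stream.
#' @return A tibble with `pfs_months`, `pfs_event`, `os_months`, `os_event`.
#' @export
generate_survival <- function(subgroup,
                              survival_params = cohort_spec()$survival_params,
                              os_residual_mean = cohort_spec()$os_residual_mean,
                              censor_window = c(60, 95), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (p in survival_params) {
    if (any(p$rates < 0)) abort("negative hazard rate",
                                class = "endomol_sim_error")
  }
  n <- length(subgroup)
  prog <- numeric(n)
  for (sg in unique(subgroup)) {
    i <- which(subgroup == sg)
    p <- survival_params[[sg]]
    prog[i] <- rpiecewise_exp(length(i), p$rates, p$breaks)
  }
  resid <- rexp(n, 1 / os_residual_mean[subgroup])
  death <- prog + resid
  cens <- runif(n, censor_window[1], censor_window[2])
  # floor at 0.1 month: registry follow-up below ~3 days is not observed
  pfs <- pmax(round(pmin(prog, cens), 2), 0.1)
  os <- pmax(round(pmin(death, cens), 2), pfs)
  tibble(
    pfs_months = pfs,
    pfs_event = prog <= cens,
    os_months = os,
    os_event = death <= cens
  )
}

#' Generate a synthetic cohort
#'
#' Draws a recruited cohort under the specification: DNA quality-control
#' failures (no GAPDH amplification), true molecular subgroups, clinical
#' covariates from the per-subgroup conditional tables, survival outcomes,
#' and marker profiles constructed as the classifier's inverse image - a
#' target MMR-d patient gets PMS2 and/or MSH6 loss with intact internal
#' control and no pathogenic POLE variant, so the ProMisE cascade recovers
#' the true label exactly for every QC-passing patient.
#'
#' @param spec A [cohort_spec()].
#' @return A list of tibbles: `patients` (validated records), `markers`
#'   (validated profiles), `true_labels` (`patient_id`, `true_subgroup`,
#'   `qc_pass`).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  n <- spec$n_recruited
  id <- sprintf("SYN%04d", seq_len(n))
  qc_fail <- runif(n) < spec$qc_failure_rate
  sg <- sample(SUBGROUPS, n, replace = TRUE, prob = spec$subgroup_probs)

  cond <- spec$conditional
  early <- logical(n)
  histology <- character(n)
  invasion <- character(n)
  lvsi <- character(n)
  nodes <- character(n)
  age <- integer(n)
  for (g in SUBGROUPS) {
    i <- which(sg == g)
    cg <- cond[[g]]
    early[i] <- runif(length(i)) < cg$early
    histology[i] <- sample(HISTOLOGIES, length(i), TRUE, cg$histology)
    invasion[i] <- sample(INVASIONS, length(i), TRUE, cg$invasion)
    lv_yes <- runif(length(i)) < cg$lvsi_yes
    lvsi[i] <- ifelse(lv_yes,
                      sample(c("focal", "substantial"), length(i), TRUE,
                             c(0.3, 0.7)),
                      "negative")
    nodes[i] <- sample(NODE_LEVELS, length(i), TRUE, cg$nodes)
    age[i] <- pmin(pmax(round(rnorm(length(i), cg$age_mean, cg$age_sd)),
                        25L), 85L)
  }
  # p53-abn tumors are never low-grade endometrioid in the emulated cohort
  stage <- ifelse(early,
                  sample(c("IA", "IB", "II"), n, TRUE, c(0.55, 0.3, 0.15)),
                  sample(c("III", "IV"), n, TRUE, c(0.75, 0.25)))
  surv <- generate_survival(sg, spec$survival_params, spec$os_residual_mean,
                            spec$censor_window)

  patients <- tibble(
    patient_id = id, age = age, figo_stage = stage, histology = histology,
    tumor_size = round(pmax(rnorm(n, 4.9, 2.5), 0.3), 1),
    invasion = invasion, lvsi = lvsi,
    cervical_stromal_invasion = runif(n) < 0.14,
    lymph_nodes = nodes,
    pfs_months = surv$pfs_months, pfs_event = surv$pfs_event,
    os_months = surv$os_months, os_event = surv$os_event
  )
  markers <- inverse_markers(id, sg, qc_fail)
  list(patients = validate_patients(patients),
       markers = validate_markers(markers),
       true_labels = tibble(patient_id = id, true_subgroup = sg,
                            qc_pass = !qc_fail))
}

# Marker profiles whose ProMisE classification equals the true subgroup.
inverse_markers <- function(id, sg, qc_fail) {
  n <- length(id)
  pms2 <- rep("intact", n)
  msh6 <- rep("intact", n)
  pct <- round(runif(n, 0.05, 0.60), 2)
  nuc <- rep(TRUE, n)
  cyt <- rep(FALSE, n)
  variants <- vector("list", n)
  variants[] <- list(tibble(protein_change = character(), exon = integer()))

  i <- which(sg == "MMR_d")
  which_lost <- sample(c("pms2", "msh6", "both"), length(i), TRUE,
                       c(0.5, 0.3, 0.2))
  pms2[i][which_lost != "msh6"] <- "lost"
  msh6[i][which_lost != "pms2"] <- "lost"

  i <- which(sg == "POLE_mut")
  hot <- sample(names(HOTSPOT_EXONS), length(i), TRUE)
  variants[i] <- lapply(hot, function(h) {
    tibble(protein_change = h, exon = HOTSPOT_EXONS[[h]])
  })

  i <- which(sg == "p53_abn")
  pattern <- sample(c("diffuse", "null", "cytoplasmic"), length(i), TRUE,
                    c(0.6, 0.3, 0.1))
  pct[i] <- ifelse(pattern == "diffuse", round(runif(length(i), 0.80, 1), 2), 0)
  nuc[i] <- pattern == "diffuse"
  cyt[i] <- pattern == "cytoplasmic"
  nuc[i][pattern == "cytoplasmic"] <- TRUE
  pct[i][pattern == "cytoplasmic"] <- round(runif(sum(pattern == "cytoplasmic"),
                                                  0.05, 0.5), 2)

  tibble(
    patient_id = id, pms2_status = pms2, msh6_status = msh6,
    ihc_internal_control_intact = TRUE,
    p53_pct_strong_nuclear = pct, p53_any_nuclear_staining = nuc,
    p53_unequivocal_cytoplasmic = cyt,
    p53_pattern_override = NA_character_,
    pole_variants = variants,
    gapdh_amplified = !qc_fail,
    a260_280 = round(runif(n, 1.80, 2.10), 2),
    a260_230 = round(runif(n, 1.85, 2.25), 2)
  )
}
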