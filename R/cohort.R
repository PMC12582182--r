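#' Simulate a phantom cohort with tau-linked cognitive scores
#'
#' Generates `n` phantom subjects (stage drawn from `stage_mix`, each with its
#' own smooth random deformation and ROI-level uptake jitter) together with
#' per-visit cognitive records. Global cognition scores follow
#' `baseline - effect * (metatemporal SUVR - 1) + noise`, clipped to `[0, 30]`
#' (MMSE baseline 28.5, MoCA 27.5); episodic memory probabilities use a
#' logistic link with the same sign convention, except for recall from
#' nondurably stored memory whose link is positive (higher tau, higher
#' nondurable recall), matching the observed direction of that measure.
#' Later visits decrement scores proportionally to baseline entorhinal /
#' inferior-temporal SUVR; exam dates are jittered around scan dates.
#'
#' @param n number of subjects (>= 2).
#' @param stage_mix named probabilities for `CN`, `MCI`, `AD` (sums to 1).
#' @param effect slope (score points per SUVR unit) linking metatemporal SUVR
#'   to the scores; 0 gives a null cohort.
#' @param noise_sd_scores Gaussian noise sd on MMSE/MoCA points.
#' @param n_visits visits per subject (1 = cross-sectional).
#' @param seed integer seed; the whole cohort is a pure function of it.
#' @param template,atlas optional output of [make_template()]; built at
#'   `shape` from `seed` when omitted.
#' @param shape,amplitude,smoothness,noise_sd phantom geometry and noise
#'   settings passed to [sample_deformation()] and [synthesize_subject()].
#' @param suvr_jitter per-ROI lognormal uptake jitter sd.
#' @param effect_long slope linking mean EC/ITG SUVR to the per-year score
#'   decline (defaults to `effect`).
#' @param volumes if `FALSE`, skip volume synthesis and compute each
#'   subject's true SUVR through the exact linear painting map; scores and
#'   SUVR are identical to the `volumes = TRUE` path.
#' @return list with `subjects` (list of `phantom_subject`, or `NULL`),
#'   `cohort` (one data.frame row per visit), `suvr` (native-truth SUVR
#'   table, baseline scan), `template`, `atlas`.
#' @export
make_cohort <- function(n, stage_mix = c(CN = 0.59, MCI = 0.33, AD = 0.08),
                        effect = 3, noise_sd_scores = 1.5, n_visits = 1L,
                        seed = 1L, template = NULL, atlas = NULL,
                        shape = c(32L, 32L, 32L), amplitude = 2,
                        smoothness = 4, noise_sd = 0.05, suvr_jitter = 0.08,
                        effect_long = effect, volumes = TRUE) {
  if (n < 2) stop("`n` must be >= 2")
  if (length(stage_mix) != 3L || any(stage_mix < 0) ||
      abs(sum(stage_mix) - 1) > 1e-8)
    stop("`stage_mix` must be 3 nonnegative probabilities summing to 1")
  if (is.null(names(stage_mix))) names(stage_mix) <- c("CN", "MCI", "AD")
  if (is.null(template) || is.null(atlas)) {
    tp <- make_template(shape, seed = seed)
    template <- tp$template
    atlas <- tp$atlas
  }
  shape <- dim(template$data)
  map <- .suvr_linear_map(template, atlas)

  plan <- withr::with_seed(as.integer(seed), {
    list(stages = sample(names(stage_mix), n, replace = TRUE,
                         prob = stage_mix),
         sub_seeds = sample.int(2^30, n),
         score_seed = sample.int(2^30, 1))
  })

  subjects <- if (volumes) vector("list", n) else NULL
  meta <- ec <- itg <- numeric(n)
  nroles <- length(map$roles)
  suvr_all <- matrix(NA_real_, n, nroles, dimnames = list(NULL, map$roles))
  for (s in seq_len(n)) {
    stg <- plan$stages[s]
    levels <- .subject_levels(atlas, stage_profile(stg), plan$sub_seeds[s],
                              suvr_jitter)
    truth <- .suvr_from_levels(map, levels)
    if (volumes) {
      fld <- sample_deformation(shape, amplitude, smoothness,
                                seed = plan$sub_seeds[s] + 1L)
      subjects[[s]] <- synthesize_subject(template, atlas, stage = stg,
                                          field = fld, noise_sd = noise_sd,
                                          seed = plan$sub_seeds[s],
                                          suvr_jitter = suvr_jitter)
    }
    suvr_all[s, ] <- truth[map$roles]
    meta[s] <- truth[["metatemporal"]]
    ec[s] <- truth[["ec"]]
    itg[s] <- truth[["itg"]]
  }
  ids <- sprintf("P%03d", seq_len(n))
  suvr_table <- data.frame(
    subject_id = rep(ids, each = nroles),
    scan_id = rep(paste0(ids, "_v1"), each = nroles),
    pipeline = "native_truth",
    roi_role = rep(map$roles, n),
    suvr = as.vector(t(suvr_all)), stringsAsFactors = FALSE)

  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  nv <- n * n_visits
  col <- function(init) rep(init, nv)
  C <- list(subject_id = col(NA_character_), visit = col(NA_integer_),
            stage = col(NA_character_), scan_date = col(NA_real_),
            exam_date = col(NA_real_), cdr_global = col(NA_real_),
            mmse = col(NA_real_), moca = col(NA_real_),
            immediate_recall_1 = col(NA_real_),
            delayed_recall_1 = col(NA_real_),
            recall_nondurable = col(NA_real_), recall_durable = col(NA_real_))
  cohort <- withr::with_seed(plan$score_seed, {
    k <- 0L
    for (s in seq_len(n)) {
      stg <- plan$stages[s]
      cdr <- switch(stg, CN = 0,
                    MCI = 0.5,
                    AD = sample(c(1, 2), 1, prob = c(0.8, 0.2)))
      dm <- meta[s] - 1
      mmse0 <- 28.5 - effect * dm + stats::rnorm(1, 0, noise_sd_scores)
      moca0 <- 27.5 - 1.1 * effect * dm + stats::rnorm(1, 0, noise_sd_scores)
      eta <- function(a, b) a + b + stats::rnorm(1, 0, 0.2 * (noise_sd_scores + 1e-12))
      im0 <- eta(0.8, -0.4 * effect * dm)
      de0 <- eta(0.4, -0.4 * effect * dm)
      nd0 <- eta(-0.2, 0.2 * effect * dm)
      du0 <- eta(1.0, -0.5 * effect * dm)
      rate <- effect_long * ((ec[s] + itg[s]) / 2 - 1)   # points per year
      for (v in seq_len(n_visits)) {
        k <- k + 1L
        yrs <- if (v == 1) 0 else (v - 1) + stats::rnorm(1, 0, 30 / 365)
        dec <- rate * yrs
        evisit <- stats::rnorm(4, 0, 0.1 * (noise_sd_scores + 1e-12))
        C$subject_id[k] <- ids[s]; C$visit[k] <- v; C$stage[k] <- stg
        C$scan_date[k] <- round(yrs * 365)
        C$exam_date[k] <- C$scan_date[k] + sample(-14:14, 1)
        C$cdr_global[k] <- cdr
        C$mmse[k] <- round(clip(mmse0 - dec + if (v > 1)
          stats::rnorm(1, 0, 0.3 * noise_sd_scores) else 0, 0, 30))
        C$moca[k] <- round(clip(moca0 - 1.1 * dec + if (v > 1)
          stats::rnorm(1, 0, 0.3 * noise_sd_scores) else 0, 0, 30))
        C$immediate_recall_1[k] <- 0.5 * stats::plogis(im0 - 0.4 * dec + evisit[1])
        C$delayed_recall_1[k] <- 0.5 * stats::plogis(de0 - 0.4 * dec + evisit[2])
        C$recall_nondurable[k] <- 0.5 * stats::plogis(nd0 + 0.2 * dec + evisit[3])
        C$recall_durable[k] <- stats::plogis(du0 - 0.5 * dec + evisit[4])
      }
    }
    as.data.frame(C, stringsAsFactors = FALSE)
  })

  list(subjects = subjects, cohort = cohort,
       suvr = suvr_table, template = template, atlas = atlas)
}
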