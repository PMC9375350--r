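# Synthetic cohort generator.
#
# Emulates a three-stratum school cohort followed over 18 months: baseline
# surface states drawn i.i.d. from a fixed distribution, each surface then
# evolved by a risk-specific 6-month Markov kernel over the eleven surface
# conditions, attendance simulated per visit with absorbing dropout. The
# latent surface trajectories keep evolving while a child is absent; only
# attended visits emit observations. Ground truth (expected stratum
# increments under the kernel, and the realized per-child transition counts
# from the latent states) is returned alongside the cohort so that
# parameter-recovery tests can compare the pipeline's output against what
# the generator actually put in.

#' Default generator configuration
#'
#' The defaults encode the cohort structure the analysis assumes: 226
#' children split 90/69/67 across low/medium/high caries risk; 126 scoreable
#' surfaces per child out of the 140 surface slots of the 28 permanent
#' teeth; baseline surface-state frequencies of a low-caries 11-12-year-old
#' school population (97.5% sound, 1.81% initial non-cavitated lesions, the
#' remainder cavitated at decreasing severity); per-visit absence and
#' absorbing dropout probabilities that reproduce a realistic ~36% attrition
#' pattern over three follow-ups; and per-risk progression rates calibrated
#' so that the expected stratum mean adjusted increments at 18 months sit
#' near 0.18/0.70/1.95 (cutoff 3-6) and 1.11/2.48/4.01 (cutoff A-6) for
#' low/medium/high risk — the increment gradient the recall rules are
#' designed to resolve. Demographics are drawn conditionally on risk so the
#' school-type association (low-risk children predominantly privately
#' schooled) is present in simulated data.
#'
#' @return A `generator_config`: list with fields `n_per_risk`,
#'   `surfaces_per_child`, `baseline_state_probs`, `progression` (per-risk
#'   rates), `shared_rates`, `absence_prob`, `dropout_prob`,
#'   `demographics`, `frailty_sd`.
#' @export
#' @examples
#' cfg <- default_config()
#' sum(cfg$n_per_risk)
default_config <- function() {
  baseline_counts <- c(SOUND = 27716, NONCAV_A = 515, CAV3 = 89, CAV4 = 26,
                       CAV5 = 55, CAV6 = 14, FILLED_SOUND = 0,
                       FILLED_NONCAV = 0, FILLED_CAV = 0, MISSING = 0,
                       CROWNED = 0)
  structure(list(
    n_per_risk = c(LOW = 90L, MEDIUM = 69L, HIGH = 67L),
    surfaces_per_child = 126L,
    baseline_state_probs = baseline_counts / sum(baseline_counts),
    # per-risk 6-month progression rates:
    #   sound_to_noncav: new initial lesion on a sound surface
    #   sound_to_cav:    direct cavitation of a sound surface
    #   noncav_to_cav:   cavitation of an initial lesion
    # calibrated against the 18-month stratum mean increment targets above
    progression = list(
      LOW    = c(sound_to_noncav = 0.00339, sound_to_cav = 0.00020,
                 noncav_to_cav = 0.0177),
      MEDIUM = c(sound_to_noncav = 0.00693, sound_to_cav = 0.000555,
                 noncav_to_cav = 0.072),
      HIGH   = c(sound_to_noncav = 0.00883, sound_to_cav = 0.00249,
                 noncav_to_cav = 0.150)
    ),
    # rates common to all risks (per 6-month step)
    shared_rates = c(
      noncav_to_sound = 0.25,     # examiner/biological reversal of code A
      cav3_to_sound = 0.03,       # examiner reversal at the cavitation margin
      cav3_to_cav4 = 0.15, cav4_to_cav5 = 0.15, cav5_to_cav6 = 0.10,
      cav3_filled = 0.05, cav4_filled = 0.08, cav5_filled = 0.10,
      cav6_filled = 0.10,         # restorative treatment -> FILLED_CAV
      cav5_missing = 0.02, cav6_missing = 0.08, cav6_crowned = 0.02,
      filled_sound_to_sound = 0.01,
      filled_noncav_to_cavfill = 0.05, filled_noncav_to_sound = 0.02,
      filled_cav_to_noncavfill = 0.02, filled_cav_missing = 0.02
    ),
    # visit-indexed (0-3): absence among active children, new-dropout hazard
    absence_prob = c(0.027, 0.112, 0.059, 0.0),
    dropout_prob = c(0.0, 0.133, 0.056, 0.011),
    # demographics conditional on risk: P(level | risk)
    demographics = list(
      sex = rbind(LOW = c(MALE = 49, FEMALE = 41),
                  MEDIUM = c(MALE = 38, FEMALE = 31),
                  HIGH = c(MALE = 36, FEMALE = 31)),
      residence = rbind(LOW = c(URBAN = 77, RURAL = 13),
                        MEDIUM = c(URBAN = 53, RURAL = 16),
                        HIGH = c(URBAN = 56, RURAL = 11)),
      school_type = rbind(LOW = c(PUBLIC = 31, PRIVATE = 59),
                          MEDIUM = c(PUBLIC = 63, PRIVATE = 6),
                          HIGH = c(PUBLIC = 55, PRIVATE = 12))
    ),
    frailty_sd = 0
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> %d children (%s), %d surfaces/child\n",
              sum(x$n_per_risk),
              paste(x$n_per_risk, collapse = "/"), x$surfaces_per_child))
  cat(sprintf("  baseline sound fraction: %.4f\n",
              x$baseline_state_probs[["SOUND"]]))
  invisible(x)
}

#' Six-month transition kernel for one risk stratum
#'
#' Builds the 11 x 11 one-step (6-month) Markov matrix over surface
#' conditions implied by a configuration's progression and shared rates.
#' `MISSING` and `CROWNED` rows are absorbing; all rows sum to 1.
#'
#' @param config A [default_config()]-shaped configuration.
#' @param risk `"LOW"`, `"MEDIUM"` or `"HIGH"`.
#' @param frailty Optional multiplier on the three progression rates
#'   (child-level frailty; 1 = none).
#' @return Row-stochastic matrix with `surface_conditions()` dimnames.
#' @export
transition_kernel <- function(config, risk, frailty = 1) {
  pr <- config$progression[[toupper(risk)]]
  if (is.null(pr)) abort_fmt("unknown risk level: %s", risk)
  pr <- pr * frailty
  r <- config$shared_rates
  # keep rows stochastic under any frailty multiplier
  s_total <- pr[["sound_to_noncav"]] + pr[["sound_to_cav"]]
  if (s_total > 1) pr[c("sound_to_noncav", "sound_to_cav")] <-
      pr[c("sound_to_noncav", "sound_to_cav")] / s_total
  pr[["noncav_to_cav"]] <- min(pr[["noncav_to_cav"]],
                               1 - r[["noncav_to_sound"]])
  s <- surface_conditions()
  K <- matrix(0, 11, 11, dimnames = list(s, s))
  set <- function(from, to, p) K[from, to] <<- p
  set("SOUND", "NONCAV_A", pr[["sound_to_noncav"]])
  set("SOUND", "CAV3", pr[["sound_to_cav"]])
  set("NONCAV_A", "SOUND", r[["noncav_to_sound"]])
  set("NONCAV_A", "CAV3", pr[["noncav_to_cav"]])
  set("CAV3", "SOUND", r[["cav3_to_sound"]])
  set("CAV3", "CAV4", r[["cav3_to_cav4"]])
  set("CAV3", "FILLED_CAV", r[["cav3_filled"]])
  set("CAV4", "CAV5", r[["cav4_to_cav5"]])
  set("CAV4", "FILLED_CAV", r[["cav4_filled"]])
  set("CAV5", "CAV6", r[["cav5_to_cav6"]])
  set("CAV5", "FILLED_CAV", r[["cav5_filled"]])
  set("CAV5", "MISSING", r[["cav5_missing"]])
  set("CAV6", "FILLED_CAV", r[["cav6_filled"]])
  set("CAV6", "MISSING", r[["cav6_missing"]])
  set("CAV6", "CROWNED", r[["cav6_crowned"]])
  set("FILLED_SOUND", "SOUND", r[["filled_sound_to_sound"]])
  set("FILLED_NONCAV", "FILLED_CAV", r[["filled_noncav_to_cavfill"]])
  set("FILLED_NONCAV", "SOUND", r[["filled_noncav_to_sound"]])
  set("FILLED_CAV", "FILLED_NONCAV", r[["filled_cav_to_noncavfill"]])
  set("FILLED_CAV", "MISSING", r[["filled_cav_missing"]])
  diag(K) <- 0
  stay <- 1 - rowSums(K)
  if (any(stay < -1e-9)) abort_fmt("invalid kernel: off-diagonal rates exceed 1")
  diag(K) <- pmax(stay, 0)
  K
}

#' Expected transition counts and increment under a configuration
#'
#' Closed-form expectations per child implied by the generator: baseline
#' states are i.i.d. from the configured distribution and each surface
#' evolves by the risk kernel, so the probability a surface classifies as
#' progression/regression/neither over `k` six-month steps is
#' `sum_i pi0[i] * (K^k)[i, j] * [class(i -> j)]`. Expected counts scale by
#' surfaces per child; the expected adjusted increment is the plug-in
#' `E[P] * E[N] / (E[R] + E[N])`.
#'
#' @param config A generator configuration.
#' @param risk Risk stratum.
#' @param months Interval (6, 12 or 18).
#' @param cutoff `"3-6"` or `"A-6"`.
#' @return List with `P`, `R`, `N` (expected counts) and `adjci`.
#' @export
expected_increment <- function(config, risk, months, cutoff) {
  cutoff <- match_cutoff(cutoff)
  k <- months_to_visit(months)
  K <- transition_kernel(config, risk)
  Kk <- diag(11)
  for (i in seq_len(k)) Kk <- Kk %*% K
  s <- surface_conditions()
  cls <- outer(collapse_state(s, cutoff), collapse_state(s, cutoff),
               classify_transition)
  pi0 <- config$baseline_state_probs[s]
  joint <- pi0 * Kk  # recycles pi0 down rows: joint[i, j] = pi0_i * Kk_ij
  n_surf <- config$surfaces_per_child
  EP <- n_surf * sum(joint[cls == "PROGRESSION"])
  ER <- n_surf * sum(joint[cls == "REGRESSION"])
  EN <- n_surf * sum(joint[cls == "NEITHER"])
  list(P = EP, R = ER, N = EN,
       adjci = if (ER + EN == 0) EP else EP * EN / (ER + EN))
}

# one vectorised 6-month step for a character state vector
step_states <- function(states, kernel) {
  out <- states
  for (s in unique(states)) {
    idx <- which(states == s)
    p <- kernel[s, ]
    nz <- which(p > 0)
    out[idx] <- colnames(kernel)[nz][
      sample.int(length(nz), length(idx), replace = TRUE, prob = p[nz])
    ]
  }
  out
}

#' Simulate a cohort
#'
#' Draws a full longitudinal cohort from a generator configuration:
#' children with risk-conditional demographics, per-visit attendance with
#' absorbing dropout, baseline surface states, and latent 6-month surface
#' evolution under the risk kernels, emitted as observations at attended
#' visits. Deterministic given `seed`.
#'
#' @param config A [default_config()]-shaped configuration.
#' @param seed Integer RNG seed.
#' @return List with `cohort` (a [caries_cohort()]) and `ground_truth`: a
#'   list with `expected` (tibble of expected per-child P/R/N/adjci per
#'   risk, interval, cutoff) and `realized` (tibble of each child's actual
#'   latent transition counts per interval and cutoff, attendance
#'   notwithstanding).
#' @export
#' @examples
#' sim <- simulate_cohort(default_config(), seed = 42)
#' sim$cohort
simulate_cohort <- function(config, seed) {
  probs <- config$baseline_state_probs
  if (abs(sum(probs) - 1) > 1e-8 || any(probs < 0)) {
    abort_fmt("baseline_state_probs must be a distribution")
  }
  for (r in risk_levels()) {
    K <- transition_kernel(config, r)
    if (any(abs(rowSums(K) - 1) > 1e-8)) abort_fmt("invalid kernel for %s", r)
  }

  withr::with_seed(as.integer(seed), {
    n_per_risk <- config$n_per_risk
    n <- sum(n_per_risk)
    ids <- sprintf("c%04d", seq_len(n))
    risk <- rep(names(n_per_risk), n_per_risk)

    draw_demo <- function(tab) {
      vapply(risk, function(r) {
        p <- tab[r, ]
        colnames(tab)[sample.int(ncol(tab), 1L, prob = p)]
      }, character(1))
    }
    children <- tibble::tibble(
      child_id = ids, risk = risk,
      sex = draw_demo(config$demographics$sex),
      residence = draw_demo(config$demographics$residence),
      school_type = draw_demo(config$demographics$school_type)
    )

    # attendance: dropout hazard first (absorbing), then absence
    att <- matrix("ATTENDED", n, 4)
    dropped <- rep(FALSE, n)
    for (k in 0:3) {
      new_drop <- !dropped & runif(n) < config$dropout_prob[k + 1]
      dropped <- dropped | new_drop
      absent <- !dropped & runif(n) < config$absence_prob[k + 1]
      att[, k + 1] <- ifelse(dropped, "DROPPED",
                             ifelse(absent, "ABSENT", "ATTENDED"))
    }
    colnames(att) <- paste0("att", 0:3)
    children <- dplyr::bind_cols(children, tibble::as_tibble(att))

    # surface slots: a fixed random subset of the 140 per child
    all_slots <- tidyr::expand_grid(tooth = permanent_teeth(),
                                    surface = tooth_surfaces())
    n_surf <- config$surfaces_per_child
    slot_idx <- unlist(lapply(seq_len(n), function(i) {
      sort(sample.int(nrow(all_slots), n_surf))
    }))
    surf <- all_slots[slot_idx, ]
    surf$child_id <- rep(ids, each = n_surf)
    surf$risk <- rep(risk, each = n_surf)

    # frailty multipliers (1 unless enabled)
    frailty <- if (config$frailty_sd > 0) {
      exp(stats::rnorm(n, -config$frailty_sd^2 / 2, config$frailty_sd))
    } else rep(1, n)

    # latent trajectories: states[, k+1] = state at visit k
    states <- matrix(NA_character_, nrow(surf), 4)
    states[, 1] <- surface_conditions()[
      sample.int(11L, nrow(surf), replace = TRUE, prob = probs)
    ]
    for (k in 1:3) {
      cur <- states[, k]
      nxt <- cur
      for (r in risk_levels()) {
        rows <- which(surf$risk == r)
        if (!length(rows)) next
        if (config$frailty_sd > 0) {
          for (i in which(risk == r)) {
            ridx <- rows[surf$child_id[rows] == ids[i]]
            nxt[ridx] <- step_states(cur[ridx],
                                     transition_kernel(config, r, frailty[i]))
          }
        } else {
          nxt[rows] <- step_states(cur[rows], transition_kernel(config, r))
        }
      }
      states[, k + 1] <- nxt
    }

    # emit observations at attended visits
    obs <- lapply(0:3, function(k) {
      ok <- att[match(surf$child_id, ids), k + 1] == "ATTENDED"
      tibble::tibble(child_id = surf$child_id[ok], visit = k,
                     tooth = surf$tooth[ok], surface = surf$surface[ok],
                     condition = states[ok, k + 1])
    })
    cohort <- caries_cohort(children, dplyr::bind_rows(obs))

    # ground truth from the latent states, ignoring attendance
    realized <- list()
    for (cutoff in cutoffs()) {
      base_c <- collapse_state(states[, 1], cutoff)
      for (k in 1:3) {
        cls <- classify_transition(base_c, collapse_state(states[, k + 1], cutoff))
        tab <- dplyr::summarise(
          dplyr::group_by(tibble::tibble(child_id = surf$child_id, cls = cls),
                          .data$child_id),
          P = sum(.data$cls == "PROGRESSION"),
          R = sum(.data$cls == "REGRESSION"),
          N = sum(.data$cls == "NEITHER"), .groups = "drop"
        )
        tab$months <- visit_months(k)
        tab$cutoff <- cutoff
        realized[[length(realized) + 1L]] <- tab
      }
    }
    realized <- dplyr::bind_rows(realized)
    realized$adjci <- adjci(realized$P, realized$R, realized$N)
    realized <- dplyr::left_join(realized, children[c("child_id", "risk")],
                                 by = "child_id")

    expected <- dplyr::bind_rows(lapply(cutoffs(), function(co) {
      dplyr::bind_rows(lapply(risk_levels(), function(r) {
        dplyr::bind_rows(lapply(c(6L, 12L, 18L), function(mo) {
          e <- expected_increment(config, r, mo, co)
          tibble::tibble(risk = r, cutoff = co, months = mo,
                         P = e$P, R = e$R, N = e$N, adjci = e$adjci)
        }))
      }))
    }))

    list(cohort = cohort,
         ground_truth = list(expected = expected, realized = realized))
  })
}
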