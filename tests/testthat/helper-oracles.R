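# Independent oracles used by the unit and acceptance tests.  These are
# deliberately naive (exhaustive enumeration, pairwise counting, threshold
# sweeps) and share no code with the implementation they check.

# exhaustive depth-1 split search on (X, g, h): enumerates every midpoint
# threshold of every feature with both missing routings, plus the explicit
# present-vs-missing split, under the same gain and tie rules as the tree
# grower (feature order, ascending thresholds, missing-left first,
# presence split last; strict improvement)
oracle_stump <- function(X, g, h, min_child_weight = 0, lambda = 1) {
  score <- function(G, H) G * G / (H + lambda)
  n <- nrow(X)
  G <- sum(g); H <- sum(h)
  base <- score(G, H)
  best <- list(feature = NA_integer_, threshold = NA_real_,
               presence = FALSE, missing_left = TRUE, gain = 0)
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    pres <- !is.na(v)
    Gp <- sum(g[pres]); Hp <- sum(h[pres])
    np <- sum(pres); nm <- n - np
    Gm <- G - Gp; Hm <- H - Hp
    vs <- sort(unique(v[pres]))
    if (length(vs) >= 2L) {
      for (k in seq_len(length(vs) - 1L)) {
        thr <- vs[k] + (vs[k + 1L] - vs[k]) / 2
        sel <- pres & v <= thr
        GLp <- sum(g[sel]); HLp <- sum(h[sel]); clp <- sum(sel)
        for (ml in c(TRUE, FALSE)) {
          gl <- GLp + if (ml) Gm else 0
          hl <- HLp + if (ml) Hm else 0
          cl <- clp + if (ml) nm else 0L
          gr <- G - gl; hr <- H - hl; cr <- n - cl
          if (cl < 1L || cr < 1L) next
          if (hl < min_child_weight || hr < min_child_weight) next
          gain <- 0.5 * (score(gl, hl) + score(gr, hr) - base)
          if (gain > 1e-12 && gain > best$gain)
            best <- list(feature = j, threshold = thr, presence = FALSE,
                         missing_left = ml, gain = gain)
        }
      }
    }
    if (np >= 1L && nm >= 1L && Hp >= min_child_weight &&
        Hm >= min_child_weight) {
      gain <- 0.5 * (score(Gp, Hp) + score(Gm, Hm) - base)
      if (gain > 1e-12 && gain > best$gain)
        best <- list(feature = j, threshold = NA_real_, presence = TRUE,
                     missing_left = TRUE, gain = gain)
    }
  }
  best
}

# AUROC by counting all positive-negative pairs (ties count one half)
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# AUPRC by explicit threshold sweep over the distinct scores (step curve,
# no interpolation)
oracle_auprc <- function(scores, labels) {
  P <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  prev_rec <- 0
  for (th in thr) {
    flag <- scores >= th
    tp <- sum(flag & labels == 1)
    prec <- tp / sum(flag)
    rec <- tp / P
    area <- area + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  area
}

# hand-built single-patient timeline rows
tl_row <- function(day, domain, code, value = NA_real_, modifier = "",
                   enc = "outpatient", pid = "X1") {
  data.frame(patient_id = pid, day = as.integer(day), domain = domain,
             feature_code = code, value = value, modifier = modifier,
             encounter_type = enc, stringsAsFactors = FALSE)
}

tl <- function(...) do.call(rbind, list(...))

# demographics rows for a hand-built timeline
tl_demo <- function(age = 60, sex = "male", race = "other", pid = "X1") {
  rbind(tl_row(0, "demographics", "age_at_onset", age, pid = pid),
        tl_row(0, "demographics", "sex", modifier = sex, pid = pid),
        tl_row(0, "demographics", "race", modifier = race, pid = pid))
}

# a serum creatinine value whose MDRD eGFR equals `egfr` for the given
# demographics (inverse of the eGFR equation)
scr_for <- function(egfr, age = 60, sex = "male", race = "other") {
  base <- 175 * age^(-0.203) * ifelse(sex == "female", 0.742, 1) *
    ifelse(race == "black", 1.212, 1)
  (egfr / base)^(-1 / 1.154)
}

# small time-constant simulation shared by several tests
small_sim <- function(n = 300, T_ = 3, seed = 7,
                      beta = c(laboratory_f2 = 0.9, diagnoses_f2 = 0.8),
                      hazard = rep(0.18, T_), ...) {
  cfg <- scenario_config(n_patients = n, n_landmarks = T_,
                         effect_vector_by_landmark = rep(list(beta), T_),
                         baseline_hazard_by_landmark = hazard,
                         seed = seed, ...)
  generate_cohort(cfg)
}
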