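#' The four embedded adaptive interventions
#'
#' Each adaptive intervention (AI) is a rule: a stage-1 treatment, continued
#' in stage 2 by responders, plus a prespecified stage-2 treatment for
#' non-responders. In the SMART these four rules are embedded through the two
#' randomizations; in the comparator RCT they are four separate arms.
#'
#' @return A `data.frame` with columns `index`, `stage1`,
#'   `nonresponder_stage2`, and a human-readable `notation`.
#' @examples
#' ai_definitions()
#' @export
ai_definitions <- function() {
  data.frame(
    index = 1:4,
    stage1 = c("NURSE", "NURSE", "APP", "APP"),
    nonresponder_stage2 = c("APP", "COMBO", "NURSE", "COMBO"),
    notation = c("(N, N^R A^(1-R))", "(N, N^R (A+N)^(1-R))",
                 "(A, A^R N^(1-R))", "(A, A^R (A+N)^(1-R))"),
    stringsAsFactors = FALSE)
}

#' Classify interim response
#'
#' A subject is a responder when their stage-1 HbA1c reduction meets or
#' exceeds the threshold (the comparison is inclusive at the threshold).
#'
#' @param delta1 Stage-1 HbA1c reduction(s), percentage points.
#' @param delta Response threshold (default 0.5).
#' @return Integer vector of 0/1 responder indicators.
#' @examples
#' classify_response(c(0.92, 0.5, 0.49)) # 1 1 0
#' @export
classify_response <- function(delta1, delta = 0.5) {
  as.integer(delta1 >= delta)
}

## Vectorized group allocation used by the trial engines.
## u: one uniform per subject; trial: trial id per subject (subjects sorted by
## trial); k groups. BALANCED assigns a within-trial random permutation to a
## near-equal multiset of labels whose surplus groups (when n %% k > 0) are
## chosen uniformly at random per trial.
.alloc_groups <- function(u, B, n, k, scheme) {
  if (scheme == "BERNOULLI") {
    g <- as.integer(floor(u * k)) + 1L
    g[g > k] <- k
    return(g)
  }
  base <- n %/% k
  rem <- n %% k
  ## per-trial random ordering of the k labels (decides surplus groups)
  og <- order(rep(seq_len(B), times = k), runif(B * k))
  perm <- ((og - 1L) %/% B) + 1L            # k labels per trial, random order
  cnt <- rep.int(base, B * k) + as.integer(rep(seq_len(k), times = B) <= rem)
  labels_sorted <- rep.int(perm, cnt)       # labels in within-trial u-order
  trial <- rep.int(seq_len(B), rep.int(n, B))
  out <- integer(B * n)
  out[order(trial, u)] <- labels_sorted
  out
}

#' Stage-1 allocation between Nurse and App
#'
#' @param n Number of subjects (>= 2).
#' @param scheme `"BALANCED"` for an exact (near-)1:1 split via random
#'   permutation, `"BERNOULLI"` for an independent fair coin per subject.
#' @return Character vector of `"NURSE"`/`"APP"` assignments.
#' @export
allocate_stage1 <- function(n, scheme = c("BALANCED", "BERNOULLI")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(n) || length(n) != 1 || n < 2)
    stop("n must be at least 2 for stage-1 allocation")
  g <- .alloc_groups(runif(n), B = 1L, n = as.integer(n), k = 2L, scheme = scheme)
  c("NURSE", "APP")[g]
}

#' Stage-2 reassignment in the SMART
#'
#' Responders continue their stage-1 treatment; non-responders are
#' re-randomized by a fair coin between the single treatment not yet tried
#' and the combination.
#'
#' @param stage1_tx Character vector of stage-1 treatments (`"APP"`/`"NURSE"`).
#' @param responder 0/1 responder indicators.
#' @return Character vector of stage-2 treatments.
#' @export
smart_reassign <- function(stage1_tx, responder) {
  s1 <- .tx_code(stage1_tx)
  if (any(s1 == .TX_COMBO)) stop("COMBO is not a valid stage-1 treatment")
  responder <- as.integer(responder)
  stopifnot(length(responder) == length(s1))
  coin <- runif(length(s1)) < 0.5
  s2 <- ifelse(responder == 1L, s1, ifelse(coin, 3L - s1, .TX_COMBO))
  .TX_LABELS[s2]
}

#' Baseline arm allocation in the four-arm RCT
#'
#' @param n Number of subjects (>= 4 under `"BALANCED"`).
#' @inheritParams allocate_stage1
#' @return Integer vector of arm indices 1-4 (matching [ai_definitions()]).
#' @export
rct_allocate <- function(n, scheme = c("BALANCED", "BERNOULLI")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a positive count")
  if (scheme == "BALANCED" && n < 4)
    stop("n must be at least 4 for balanced four-arm allocation")
  .alloc_groups(runif(n), B = 1L, n = as.integer(n), k = 4L, scheme = scheme)
}

#' Embedded adaptive interventions consistent with SMART records
#'
#' A SMART responder's observed pathway is consistent with the two embedded
#' AIs sharing their stage-1 treatment; a non-responder's pathway pins down
#' exactly one AI via the stage-2 assignment.
#'
#' @param records A data frame of SMART subject records with columns
#'   `stage1_tx`, `responder`, `stage2_tx`.
#' @return A list (one element per record) of integer vectors of AI indices.
#' @export
consistent_ais <- function(records) {
  s1 <- .tx_code(records$stage1_tx)
  s2 <- .tx_code(records$stage2_tx)
  r <- as.integer(records$responder)
  if (any(r == 1L & s2 != s1))
    stop("inconsistent record: responder whose stage-2 treatment differs from stage 1")
  if (any(r == 0L & s2 == s1))
    stop("inconsistent record: non-responder continuing their stage-1 treatment")
  lapply(seq_along(s1), function(i) {
    if (r[i] == 1L) {
      if (s1[i] == .TX_NURSE) c(1L, 2L) else c(3L, 4L)
    } else {
      .ai_of_nonresponder(s1[i], s2[i])
    }
  })
}

## single AI index of a non-responder pathway (internal integer codes)
.ai_of_nonresponder <- function(s1, s2) {
  ifelse(s1 == .TX_NURSE, ifelse(s2 == .TX_APP, 1L, 2L),
         ifelse(s2 == .TX_NURSE, 3L, 4L))
}
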