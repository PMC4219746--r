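# Maximum-likelihood integration of noisy perturbation evidence into a
# signed literature GRN.
#
# Each observation is reduced to a sign: s(perturbation) * s(effect) with
# s(gain)=+1, s(loss)=-1, s(up)=+1, s(down)=-1 and any "no change" effect
# forcing sign 0. A regulator-target pair (RTP) with observations of both
# sign +1 and -1 in any context is conflicting and removed. For the rest,
# the mode of regulation M in {activating, none, inhibiting} maximises
# L(M) = prod_i P(obs_i | M), computed in log space.

modes <- c("activating", "none", "inhibiting")
obs_levels <- c("+1", "0", "-1")

#' Conditional-probability noise model for perturbation evidence
#'
#' `alpha` is the probability of a correct experimental observation and
#' `beta` the probability of observing "no change" when a true effect
#' exists (detection insensitivity). The remaining mass is completed
#' column-stochastically: wrong-sign mass `1 - alpha - beta` under an
#' activating/inhibiting mode, and a symmetric split `(1 - alpha)/2` on
#' each nonzero sign under mode "none".
#'
#' @param alpha probability of a correct observation (default 0.9).
#' @param beta probability of an insensitive "no change" observation when
#'   a true effect exists (default 0.05). Requires `alpha > beta >= 0` and
#'   `alpha + beta <= 1`.
#' @return a `noise_model` holding the 3x3 matrix `P` with rows
#'   `obs in {+1, 0, -1}` and columns `M in {activating, none, inhibiting}`.
#' @export
noise_model <- function(alpha = 0.9, beta = 0.05) {
  if (!(alpha > beta && beta >= 0 && alpha + beta <= 1))
    stop("need alpha > beta >= 0 and alpha + beta <= 1")
  wrong <- max(0, 1 - alpha - beta)  # guard tiny negative float residue
  P <- cbind(activating = c(alpha, beta, wrong),
             none = c((1 - alpha) / 2, alpha, (1 - alpha) / 2),
             inhibiting = c(wrong, beta, alpha))
  rownames(P) <- obs_levels
  stopifnot(all(abs(colSums(P) - 1) < 1e-12))
  structure(list(alpha = alpha, beta = beta, P = P), class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("noise_model: alpha=%.3f beta=%.3f\n", x$alpha, x$beta))
  print(round(x$P, 4))
  invisible(x)
}

sign_of <- c(gain = 1L, loss = -1L, up = 1L, none = 0L, down = -1L)

#' Canonicalize evidence records to signed observations
#'
#' @param records validated evidence data.frame (see
#'   [read_evidence_table()]).
#' @return data.frame with `regulator`, `target`, `sign` (+1/0/-1),
#'   `tissue_perturbed`, `stage`.
#' @export
canonicalize_evidence <- function(records) {
  data.frame(regulator = records$regulator, target = records$target,
             sign = unname(sign_of[records$perturbation] *
                             sign_of[records$effect]),
             tissue_perturbed = records$tissue_perturbed,
             stage = records$stage, stringsAsFactors = FALSE)
}

#' Group signed observations into RTP sign counts
#'
#' @param observations output of [canonicalize_evidence()].
#' @return data.frame with one row per (regulator, target) pair and sign
#'   counts `n_plus`, `n_zero`, `n_minus`.
#' @export
collect_rtps <- function(observations) {
  key <- interaction(observations$regulator, observations$target,
                     drop = TRUE, sep = "\r")
  agg <- function(s) as.vector(tapply(observations$sign == s, key, sum))
  first <- !duplicated(key)
  out <- data.frame(regulator = observations$regulator[first],
                    target = observations$target[first],
                    stringsAsFactors = FALSE)
  out <- out[order(match(key[first], levels(key))), , drop = FALSE]
  out$n_plus <- agg(1L); out$n_zero <- agg(0L); out$n_minus <- agg(-1L)
  out$n_evidence <- out$n_plus + out$n_zero + out$n_minus
  rownames(out) <- NULL
  out
}

#' Remove RTPs with opposing regulatory evidence
#'
#' An RTP is conflicting if its observation multiset contains both sign
#' +1 and sign -1 in any tissue or time point; sign-0 observations are
#' neutral and never constitute opposition.
#'
#' @param rtps output of [collect_rtps()].
#' @return list with `kept` and `removed` data.frames; `removed` rows have
#'   `status = "conflicting"`.
#' @export
filter_conflicts <- function(rtps) {
  conflicting <- rtps$n_plus > 0 & rtps$n_minus > 0
  removed <- rtps[conflicting, , drop = FALSE]
  if (nrow(removed)) removed$status <- "conflicting"
  message("conflict filter: kept ", sum(!conflicting), ", removed ",
          sum(conflicting), " RTP(s)")
  list(kept = rtps[!conflicting, , drop = FALSE], removed = removed)
}

#' Per-mode log-likelihood of an observation multiset
#'
#' @param n_plus,n_zero,n_minus sign counts (vectors recycle together).
#' @param noise a [noise_model()].
#' @return matrix with one row per input and columns `activating`,
#'   `none`, `inhibiting`. Zero-probability factors contribute `-Inf`.
#' @export
mode_loglik <- function(n_plus, n_zero, n_minus, noise) {
  counts <- cbind(n_plus, n_zero, n_minus)
  logP <- log(noise$P)  # rows +1,0,-1
  out <- matrix(0, nrow(counts), 3, dimnames = list(NULL, modes))
  for (m in 1:3) {
    for (r in 1:3) {
      term <- counts[, r] * logP[r, m]
      term[counts[, r] == 0] <- 0  # 0 * -Inf is no evidence, not NaN
      out[, m] <- out[, m] + term
    }
  }
  out
}

#' Infer the mode of regulation for one observation multiset
#'
#' Likelihood ties are resolved conservatively: the reported mode is
#' `"none"` and the status is `"tie"` — causality is never asserted on
#' ambiguous evidence.
#'
#' @param signs integer vector of observation signs in \{+1, 0, -1\}.
#' @param noise a [noise_model()].
#' @return list with `mode`, `status` (`"resolved"` or `"tie"`) and the
#'   named per-mode `loglik` vector.
#' @export
infer_mode <- function(signs, noise) {
  if (!length(signs)) stop("empty observation multiset")
  stopifnot(all(signs %in% c(-1L, 0L, 1L)))
  ll <- mode_loglik(sum(signs == 1), sum(signs == 0), sum(signs == -1),
                    noise)[1, ]
  top <- which(ll == max(ll))
  if (length(top) > 1) list(mode = "none", status = "tie", loglik = ll)
  else list(mode = modes[top], status = "resolved", loglik = ll)
}

#' Infer modes for a table of RTP sign counts
#'
#' @param rtps conflict-free RTP table ([filter_conflicts()]`$kept`).
#' @param noise a [noise_model()].
#' @return the input with columns `loglik_act`, `loglik_none`,
#'   `loglik_inhib`, `mode`, `status` appended.
#' @export
infer_modes <- function(rtps, noise) {
  if (any(rtps$n_plus > 0 & rtps$n_minus > 0))
    stop("conflicting RTP(s) present; run filter_conflicts() first")
  if (any(rtps$n_evidence == 0)) stop("RTP with empty observation multiset")
  ll <- mode_loglik(rtps$n_plus, rtps$n_zero, rtps$n_minus, noise)
  is_max <- ll == ll[cbind(seq_len(nrow(ll)), max.col(ll))]
  tie <- rowSums(is_max) > 1
  rtps$loglik_act <- ll[, 1]; rtps$loglik_none <- ll[, 2]
  rtps$loglik_inhib <- ll[, 3]
  rtps$mode <- modes[max.col(ll, ties.method = "first")]
  rtps$mode[tie] <- "none"
  rtps$status <- ifelse(tie, "tie", "resolved")
  rtps
}

#' Split resolved RTPs into signed edges and the no-effect negative set
#'
#' Activating/inhibiting RTPs become signed edges; `mode == "none"` pairs
#' are returned separately as the negative set used for specificity
#' estimation. Self-loops are excluded from both lists (they are only
#' meaningful at the raw-evidence level).
#'
#' @param rtps output of [infer_modes()].
#' @return list with `edges` and `negatives` data.frames (columns:
#'   regulator, target, mode, sign, n_evidence, loglik_*, status).
#' @export
build_literature_network <- function(rtps) {
  if (is.null(rtps$mode) || anyNA(rtps$mode))
    stop("unresolved RTP(s): run infer_modes() first")
  self <- rtps$regulator == rtps$target
  if (any(self))
    message("excluding ", sum(self), " self-loop RTP(s) from the network")
  rtps <- rtps[!self, , drop = FALSE]
  rtps$sign <- c(activating = 1L, none = 0L, inhibiting = -1L)[rtps$mode]
  list(edges = rtps[rtps$mode != "none", , drop = FALSE],
       negatives = rtps[rtps$mode == "none", , drop = FALSE])
}

#' Run the full evidence-integration pipeline
#'
#' Canonicalizes records, removes conflicting RTPs, infers modes by
#' maximum likelihood and partitions the result into the signed
#' literature network and its no-effect negative set. A per-context
#' (tissue, stage) mode table is attached for tissue-specificity reports;
#' mode inference itself pools evidence across contexts.
#'
#' @param records validated evidence data.frame.
#' @param noise a [noise_model()].
#' @return list: `edges`, `negatives`, `removed_conflicts`, `rtps`
#'   (the resolved table) and `context_modes`.
#' @export
literature_grn <- function(records, noise = noise_model()) {
  obs <- canonicalize_evidence(records)
  split_pairs <- filter_conflicts(collect_rtps(obs))
  resolved <- infer_modes(split_pairs$kept, noise)
  net <- build_literature_network(resolved)
  ctx_key <- interaction(obs$regulator, obs$target, obs$tissue_perturbed,
                         obs$stage, drop = TRUE, sep = "\r")
  ctx <- collect_rtps(within(obs, {
    regulator <- paste(regulator, tissue_perturbed, stage, sep = "\r")
  }))
  parts <- do.call(rbind, strsplit(ctx$regulator, "\r", fixed = TRUE))
  context_modes <- data.frame(regulator = parts[, 1], target = ctx$target,
                              tissue_perturbed = parts[, 2],
                              stage = parts[, 3],
                              n_plus = ctx$n_plus, n_zero = ctx$n_zero,
                              n_minus = ctx$n_minus,
                              stringsAsFactors = FALSE)
  list(edges = net$edges, negatives = net$negatives,
       removed_conflicts = split_pairs$removed, rtps = resolved,
       context_modes = context_modes)
}
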