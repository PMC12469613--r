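# Clustered event-based model of disease progression.
#
# Each biomarker has a pre-event and a post-event Gaussian distribution. A
# subtype is an ordered partition of the biomarkers into S stage-clusters; a
# subject at stage s (stage support 0..S, 0 = no events yet) has undergone
# every event in clusters 1..s. Subjects carry posteriors over (subtype,
# stage); orderings are point-estimated by EM and their uncertainty is
# quantified by Metropolis sampling over partitions.

#' Model configuration
#'
#' @param n_subtypes Number of subtypes K (1..5).
#' @param n_stages Number of stages S (1..6).
#' @param min_cluster Minimum biomarkers per stage-cluster (>= 5, default 10).
#' @param em_iters EM iteration cap.
#' @param mcmc_burnin,mcmc_final Discarded and retained Metropolis iterations.
#' @param seed Integer seed.
#' @param tol EM convergence tolerance on the total log-likelihood.
#' @param n_starts Number of EM starts: the first is a deterministic
#'   principal-direction split, the rest use seeded random orderings (the
#'   subtype likelihood is multimodal in the orderings, so restarts are
#'   needed to break symmetry between subtypes). The best final
#'   log-likelihood wins. Default `1 + 3 * (n_subtypes - 1)`: a single
#'   subtype rarely benefits from restarts.
#' @return An `eb_config` list.
#' @export
ebm_config <- function(n_subtypes = 1L, n_stages = 4L, min_cluster = 10L,
                       em_iters = 100L, mcmc_burnin = 10000L,
                       mcmc_final = 100000L, seed = 42L, tol = 1e-4,
                       n_starts = 1L + 3L * (as.integer(n_subtypes) - 1L)) {
  cfg <- list(n_subtypes = as.integer(n_subtypes),
              n_stages = as.integer(n_stages),
              min_cluster = as.integer(min_cluster),
              em_iters = as.integer(em_iters),
              mcmc_burnin = as.integer(mcmc_burnin),
              mcmc_final = as.integer(mcmc_final),
              seed = as.integer(seed), tol = tol,
              n_starts = max(1L, as.integer(n_starts)))
  class(cfg) <- "eb_config"
  cfg
}

#' Fit pre- and post-event distributions per biomarker
#'
#' With a designated baseline class, pre-event moments come from baseline
#' subjects and post-event moments from the most advanced class (the last in
#' `outcome_order`). Without a baseline (or when either class has fewer than
#' three subjects, with a warning), a two-component Gaussian mixture is fit
#' per biomarker and the lower-mean component is taken as pre-event.
#' Standard deviations are floored at `1e-3` of the feature range.
#'
#' @param cohort An `eb_cohort`.
#' @return An `eb_event_dists` data.frame with columns `feature`, `mu_pre`,
#'   `sd_pre`, `mu_post`, `sd_post`.
#' @export
fit_event_distributions <- function(cohort) {
  X <- cohort$X
  use_moments <- FALSE
  if (!is.null(cohort$baseline)) {
    advanced <- utils::tail(cohort$outcome_order, 1L)
    pre_rows <- cohort$meta$Outcome == cohort$baseline
    post_rows <- cohort$meta$Outcome == advanced
    if (sum(pre_rows) >= 3L && sum(post_rows) >= 3L) {
      use_moments <- TRUE
    } else {
      eb_warning("eb_model_warning", paste0(
        "baseline or advanced class has fewer than 3 subjects; ",
        "falling back to per-biomarker mixture fits"))
    }
  }
  M <- ncol(X)
  mu_pre <- mu_post <- sd_pre <- sd_post <- numeric(M)
  for (j in seq_len(M)) {
    x <- X[, j]
    rng <- diff(range(x))
    floor_sd <- max(1e-3 * rng, 1e-3)
    if (use_moments) {
      mu_pre[j] <- mean(x[pre_rows]);  sd_pre[j] <- stats::sd(x[pre_rows])
      mu_post[j] <- mean(x[post_rows]); sd_post[j] <- stats::sd(x[post_rows])
    } else if (rng < .Machine$double.eps) {
      mu_pre[j] <- mu_post[j] <- mean(x)
      sd_pre[j] <- sd_post[j] <- 0
    } else {
      fit <- tryCatch(
        Mclust(x, G = 2, modelNames = "E", verbose = FALSE),
        error = function(e) NULL)
      if (is.null(fit)) {
        med <- stats::median(x)
        lo <- x <= med; hi <- x > med
        mu_pre[j] <- mean(x[lo]); sd_pre[j] <- stats::sd(x[lo])
        mu_post[j] <- mean(x[hi]); sd_post[j] <- stats::sd(x[hi])
      } else {
        mus <- fit$parameters$mean
        sds <- sqrt(rep_len(fit$parameters$variance$sigmasq, 2L))
        lo <- which.min(mus); hi <- which.max(mus)
        mu_pre[j] <- mus[lo]; sd_pre[j] <- sds[lo]
        mu_post[j] <- mus[hi]; sd_post[j] <- sds[hi]
      }
    }
    sd_pre[j] <- max(sd_pre[j], floor_sd, na.rm = TRUE)
    sd_post[j] <- max(sd_post[j], floor_sd, na.rm = TRUE)
  }
  structure(data.frame(feature = colnames(X), mu_pre = mu_pre,
                       sd_pre = sd_pre, mu_post = mu_post, sd_post = sd_post,
                       stringsAsFactors = FALSE),
            class = c("eb_event_dists", "data.frame"))
}

# Per-subject, per-biomarker log densities; D = log post - log pre.
.density_logs <- function(X, dists) {
  stopifnot(identical(colnames(X), dists$feature))
  n <- nrow(X); M <- ncol(X)
  logpre <- matrix(stats::dnorm(X,
                                matrix(dists$mu_pre, n, M, byrow = TRUE),
                                matrix(dists$sd_pre, n, M, byrow = TRUE),
                                log = TRUE), n, M)
  logpost <- matrix(stats::dnorm(X,
                                 matrix(dists$mu_post, n, M, byrow = TRUE),
                                 matrix(dists$sd_post, n, M, byrow = TRUE),
                                 log = TRUE), n, M)
  dimnames(logpre) <- dimnames(logpost) <- dimnames(X)
  list(logpre = logpre, logpost = logpost, D = logpost - logpre,
       base = rowSums(logpre))
}

# N x S matrix of per-cluster sums of D for cluster assignment z (1..S).
.cluster_sums <- function(D, z, S) {
  C <- matrix(0, nrow(D), S)
  for (c in seq_len(S)) {
    in_c <- which(z == c)
    if (length(in_c)) C[, c] <- rowSums(D[, in_c, drop = FALSE])
  }
  C
}

# N x (S+1) stage log-likelihood matrix: column s+1 is log L(x | stage s).
.stage_logliks <- function(base, C) {
  S <- ncol(C)
  cum <- C %*% upper.tri(diag(S), diag = TRUE)
  cbind(base, base + cum, deparse.level = 0)
}

#' Log-likelihood of one subject at a given subtype stage
#'
#' `log L(x | z, s)` sums the post-event log density for biomarkers whose
#' cluster index is at most `s` and the pre-event log density for the rest.
#' Stage 0 means no events have occurred.
#'
#' @param x Named numeric vector (one subject, all model biomarkers).
#' @param z Integer cluster assignment per biomarker (1..S), named.
#' @param s Stage in `0..S`.
#' @param dists An `eb_event_dists`.
#' @return Scalar log-likelihood.
#' @export
subject_stage_loglik <- function(x, z, s, dists) {
  stopifnot(length(x) == nrow(dists))
  post <- z <= s
  sum(stats::dnorm(x[post], dists$mu_post[post], dists$sd_post[post],
                   log = TRUE)) +
    sum(stats::dnorm(x[!post], dists$mu_pre[!post], dists$sd_pre[!post],
                     log = TRUE))
}

#' Total log-likelihood of a partition (single subtype)
#'
#' Observed-data log-likelihood of an ordered partition under a uniform
#' stage prior over `0..S`, optionally weighting subjects (e.g. by subtype
#' responsibility).
#'
#' @param X Subject-by-biomarker matrix restricted to the model's features.
#' @param dists An `eb_event_dists` matching the columns of `X`.
#' @param z Cluster assignment vector (1..S) per biomarker.
#' @param weights Optional per-subject weights (default 1).
#' @return Scalar log-likelihood.
#' @export
partition_loglik <- function(X, dists, z, weights = NULL) {
  S <- max(z)
  dl <- .density_logs(X, dists)
  L <- .stage_logliks(dl$base, .cluster_sums(dl$D, z, S))
  ll_n <- row_logsumexp(L) - log(S + 1)
  if (is.null(weights)) sum(ll_n) else sum(weights * ll_n)
}

#' Expectation step
#'
#' Computes per-subject responsibilities `r[n, k, s]` proportional to
#' `pi_k * L(x_n | subtype k, stage s)` with a uniform stage prior over
#' `0..S`, normalised per subject in log space.
#'
#' @param dl Precomputed density logs (internal) or an `eb_cohort` plus
#'   `dists` via [run_em()]; exported for testing with explicit pieces.
#' @param partitions List of K cluster-assignment vectors.
#' @param pi Subtype mixture weights (non-negative, summing to 1).
#' @param S Number of stages.
#' @return List with `r` (N x K x (S+1) array) and `loglik` (total observed
#'   log-likelihood).
#' @keywords internal
.e_step <- function(dl, partitions, pi, S) {
  K <- length(partitions)
  n <- length(dl$base)
  logr <- array(-Inf, c(n, K, S + 1L))
  for (k in seq_len(K)) {
    if (pi[k] <= 0) next  # zero-prior subtype keeps log-responsibility -Inf
    L <- .stage_logliks(dl$base, .cluster_sums(dl$D, partitions[[k]], S))
    logr[, k, ] <- L + log(pi[k]) - log(S + 1)
  }
  flat <- matrix(logr, n, K * (S + 1L))
  lse <- row_logsumexp(flat)
  r <- array(exp(flat - lse), c(n, K, S + 1L))
  list(r = r, loglik = sum(lse))
}

#' E-step over a cohort
#'
#' @param cohort An `eb_cohort` restricted to the model's biomarkers.
#' @param partitions List of K cluster-assignment vectors (values 1..S).
#' @param dists An `eb_event_dists`.
#' @param pi Subtype mixture weights.
#' @return List with responsibility array `r` (subjects x subtypes x stages
#'   0..S) and `loglik`.
#' @export
e_step <- function(cohort, partitions, dists, pi) {
  S <- max(partitions[[1L]])
  dl <- .density_logs(cohort$X, dists)
  .e_step(dl, partitions, pi, S)
}

# Weighted pairwise event-precedence ordering (the quadratic sorting step).
# E is the N x M event-evidence matrix; w weighs subjects. A[i, j]
# accumulates, over subjects, the positive part of the evidence margin
# e_i - e_j, so a comparison is decided by subjects in whom one event has
# clearly occurred and the other clearly has not, while subjects
# uninformative about the pair (both events present or both absent)
# contribute almost nothing. Event i precedes event j when its net margin
# wins; events are ranked by Copeland score (number of pairwise wins), with
# total margin and then incumbent position as tie-breaks.
.precedence_order <- function(E, w, incumbent) {
  M <- ncol(E)
  A <- matrix(0, M, M)
  for (n in seq_len(nrow(E))) {
    if (w[n] <= 0) next
    A <- A + w[n] * pmax(outer(E[n, ], E[n, ], `-`), 0)
  }
  net <- A - t(A)
  wins <- rowSums(net > 0) + 0.5 * rowSums(net == 0) - 0.5
  borda <- rowSums(A)
  order(-wins, -borda, match(seq_len(M), incumbent), method = "radix")
}

# Near-equal contiguous partition of an ordering into S clusters
# (remainder spread over the earliest clusters).
.equal_partition <- function(ord, S) {
  M <- length(ord)
  sizes <- rep(M %/% S, S)
  extra <- M %% S
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  z <- integer(M)
  z[ord] <- rep.int(seq_len(S), sizes)
  z
}

#' Maximisation step
#'
#' Per subtype: biomarkers are ordered by weighted pairwise event precedence
#' (for each pair of biomarkers, a vote over subjects — weighted by subtype
#' responsibility — on which event shows more evidence of having occurred),
#' then cut into S contiguous near-equal stage-clusters; mixture weights are
#' updated as mean subtype responsibility. Ties keep the incumbent order.
#'
#' @param dl Precomputed density logs.
#' @param r Responsibility array from the E-step.
#' @param partitions Incumbent partitions (tie-break reference).
#' @param S Number of stages.
#' @return List with `partitions`, `pi`, and `empty` (indices of subtypes
#'   with less than one subject-equivalent of responsibility, flagged for
#'   safeguard merging).
#' @keywords internal
.m_step <- function(dl, r, partitions, S) {
  K <- dim(r)[2L]
  E <- stats::plogis(dl$D)
  new_parts <- vector("list", K)
  pi <- numeric(K)
  empty <- integer(0)
  for (k in seq_len(K)) {
    w <- rowSums(r[, k, , drop = FALSE], dims = 1L)
    pi[k] <- mean(w)
    if (sum(w) < 1) empty <- c(empty, k)
    incumbent <- order(partitions[[k]], method = "radix")
    ord <- .precedence_order(E, w, incumbent)
    new_parts[[k]] <- .equal_partition(ord, S)
    names(new_parts[[k]]) <- colnames(dl$D)
  }
  pi <- pi / sum(pi)
  list(partitions = new_parts, pi = pi, empty = empty)
}

#' M-step over a cohort
#'
#' @inheritParams e_step
#' @param posterior Responsibility array from [e_step()].
#' @return Updated `partitions`, `pi`, and `empty` subtype flags.
#' @export
m_step <- function(cohort, posterior, dists, partitions) {
  S <- max(partitions[[1L]])
  dl <- .density_logs(cohort$X, dists)
  .m_step(dl, posterior, partitions, S)
}

# Deterministic subtype initialisation: subjects are split into K groups by
# quantiles of their first principal-component score; each group seeds one
# subtype's initial ordering by mean event evidence.
.init_model <- function(dl, K, S, X) {
  n <- nrow(X)
  if (K == 1L) {
    groups <- rep(1L, n)
  } else {
    Xc <- scale(X, center = TRUE, scale = FALSE)
    pc1 <- svd(Xc, nu = 1L, nv = 0L)$u[, 1L]
    qs <- stats::quantile(pc1, probs = seq(0, 1, length.out = K + 1L))
    groups <- as.integer(cut(pc1, breaks = unique(qs), include.lowest = TRUE))
    groups[is.na(groups)] <- 1L
    if (length(unique(groups)) < K)
      groups <- rep_len(seq_len(K), n)  # degenerate PC scores
  }
  E <- stats::plogis(dl$D)
  partitions <- lapply(seq_len(K), function(k) {
    rows <- groups == k
    ev <- colMeans(E[rows, , drop = FALSE])
    ord <- order(-ev, colnames(E), method = "radix")
    z <- .equal_partition(ord, S)
    names(z) <- colnames(E)
    z
  })
  pi <- as.numeric(table(factor(groups, seq_len(K))) / n)
  list(partitions = partitions, pi = pi)
}

#' Fit the event-based model by EM
#'
#' Alternates E- and M-steps from a deterministic, seeded initialisation
#' (subjects split on their first principal direction) until the total
#' log-likelihood changes by less than `tol` or `em_iters` is reached. An
#' M-step whose new orderings would lower the observed log-likelihood is
#' reverted (mixture weights are still updated), so the trace is
#' non-decreasing up to tolerance.
#'
#' @param cohort An `eb_cohort`, already restricted to the model biomarkers.
#' @param cfg An `eb_config`.
#' @param dists Optional precomputed `eb_event_dists`.
#' @return An `eb_model`: `partitions` (list of K named cluster-assignment
#'   vectors), `pi`, `posterior` (N x K x (S+1) responsibility array),
#'   `loglik_trace`, `dists`, `config`, `cohort`, `empty_subtypes`.
#' @export
run_em <- function(cohort, cfg, dists = NULL) {
  S <- cfg$n_stages; K <- cfg$n_subtypes
  M <- ncol(cohort$X)
  if (M < S * cfg$min_cluster)
    eb_abort("eb_config_error", sprintf(
      "%d biomarkers cannot fill %d stages at min_cluster %d (need >= %d)",
      M, S, cfg$min_cluster, S * cfg$min_cluster))
  set.seed(cfg$seed)
  if (is.null(dists)) dists <- fit_event_distributions(cohort)
  dl <- .density_logs(cohort$X, dists)
  best <- NULL
  for (start in seq_len(cfg$n_starts)) {
    set.seed(cfg$seed + start - 1L)
    if (start == 1L) {
      st <- .init_model(dl, K, S, cohort$X)
      partitions <- st$partitions; pi <- st$pi
    } else {
      # Exemplar seeding: each subtype's initial ordering comes from one
      # random mid-burden subject, whose event evidence ranks its own
      # (subtype-specific) early events first. This breaks the symmetry
      # between subtypes far more effectively than uniform random orderings.
      E <- stats::plogis(dl$D)
      burden <- rowSums(E)
      qs <- stats::quantile(burden, c(0.2, 0.8))
      interior <- which(burden > qs[1L] & burden < qs[2L])
      if (length(interior) < K) interior <- seq_along(burden)
      seeds_n <- sample(interior, K)
      partitions <- lapply(seeds_n, function(n0) {
        ord <- order(-E[n0, ], colnames(E), method = "radix")
        z <- .equal_partition(ord, S)
        names(z) <- colnames(cohort$X)
        z
      })
      pi <- rep(1 / K, K)
    }
    es <- .e_step(dl, partitions, pi, S)
    trace <- es$loglik
    empty <- integer(0)
    for (it in seq_len(cfg$em_iters)) {
      ms <- .m_step(dl, es$r, partitions, S)
      es_new <- .e_step(dl, ms$partitions, ms$pi, S)
      if (!is.finite(es_new$loglik))
        eb_abort("eb_model_error", "non-finite log-likelihood during EM")
      if (es_new$loglik < utils::tail(trace, 1L) - 1e-8) {
        # keep incumbent orderings; mixture-weight update alone cannot decrease
        es_new <- .e_step(dl, partitions, ms$pi, S)
        ms$partitions <- partitions
      }
      partitions <- ms$partitions; pi <- ms$pi; empty <- ms$empty
      delta <- es_new$loglik - utils::tail(trace, 1L)
      trace <- c(trace, es_new$loglik)
      es <- es_new
      if (abs(delta) < cfg$tol) break
    }
    if (is.null(best) || utils::tail(trace, 1L) > utils::tail(best$loglik_trace, 1L)) {
      best <- list(partitions = partitions, pi = pi, posterior = es$r,
                   loglik_trace = trace, empty_subtypes = empty)
    }
  }
  structure(c(best, list(dists = dists, config = cfg, cohort = cohort)),
            class = "eb_model")
}

#' @method print eb_model
#' @export
print.eb_model <- function(x, ...) {
  cat(sprintf("<eb_model> %d subtype(s), %d stages, %d biomarkers, %d subjects\n",
              length(x$partitions), x$config$n_stages,
              ncol(x$cohort$X), nrow(x$cohort$X)))
  cat(sprintf("  log-likelihood: %.2f after %d EM iterations\n",
              utils::tail(x$loglik_trace, 1L), length(x$loglik_trace) - 1L))
  cat("  mixture weights:", paste(sprintf("%.3f", x$pi), collapse = ", "), "\n")
  invisible(x)
}

#' Positional confidence by Metropolis sampling over partitions
#'
#' For each subtype, samples ordered partitions around the EM solution with
#' two proposal moves — relocating one biomarker to an adjacent stage-cluster
#' (respecting the minimum cluster size) or swapping two biomarkers between
#' adjacent clusters — accepted with probability `min(1, exp(delta
#' log-likelihood))`. Subjects are weighted by subtype responsibility. After
#' `mcmc_burnin` discarded iterations, `mcmc_final` retained samples yield
#' `P[m, s]`, the frequency with which biomarker `m` occupies stage `s`.
#'
#' @param model An `eb_model` from [run_em()].
#' @return An `eb_confidence` list: `P` (list of M x S matrices, rows
#'   summing to 1), `accept_rate` per subtype.
#' @export
run_mcmc <- function(model) {
  cfg <- model$config
  S <- cfg$n_stages
  dl <- .density_logs(model$cohort$X, model$dists)
  M <- ncol(model$cohort$X)
  set.seed(cfg$seed + 1000L)
  Ps <- list(); acc_rates <- numeric(length(model$partitions))
  for (k in seq_along(model$partitions)) {
    z <- model$partitions[[k]]
    if (S == 1L) {  # a single stage admits exactly one partition
      Ps[[k]] <- matrix(1, M, 1L, dimnames = list(names(z), NULL))
      acc_rates[k] <- 0
      next
    }
    w <- rowSums(model$posterior[, k, , drop = FALSE], dims = 1L)
    C <- .cluster_sums(dl$D, z, S)
    ll <- sum(w * (row_logsumexp(.stage_logliks(dl$base, C)) - log(S + 1)))
    sizes <- tabulate(z, S)
    counts <- matrix(0, M, S, dimnames = list(names(z), NULL))
    n_acc_burn <- 0L; n_acc <- 0L
    total <- cfg$mcmc_burnin + cfg$mcmc_final
    for (it in seq_len(total)) {
      C_new <- C; z_new <- z; sizes_new <- sizes
      if (stats::runif(1) < 0.5) {
        m <- sample.int(M, 1L)
        c0 <- z[m]
        dirs <- c(if (c0 > 1L) c0 - 1L, if (c0 < S) c0 + 1L)
        c1 <- if (length(dirs) == 1L) dirs else sample(dirs, 1L)
        if (sizes[c0] - 1L < cfg$min_cluster) {
          c1 <- c0  # move blocked by the cluster-size floor
        } else {
          z_new[m] <- c1
          C_new[, c0] <- C[, c0] - dl$D[, m]
          C_new[, c1] <- C[, c1] + dl$D[, m]
          sizes_new[c0] <- sizes[c0] - 1L
          sizes_new[c1] <- sizes[c1] + 1L
        }
      } else {
        b <- sample.int(S - 1L, 1L)
        m1 <- sample(which(z == b), 1L)
        m2 <- sample(which(z == b + 1L), 1L)
        z_new[m1] <- b + 1L; z_new[m2] <- b
        d12 <- dl$D[, m1] - dl$D[, m2]
        C_new[, b] <- C[, b] - d12
        C_new[, b + 1L] <- C[, b + 1L] + d12
      }
      if (!identical(z_new, z)) {
        ll_new <- sum(w * (row_logsumexp(.stage_logliks(dl$base, C_new)) -
                             log(S + 1)))
        if (log(stats::runif(1)) < ll_new - ll) {
          z <- z_new; C <- C_new; sizes <- sizes_new; ll <- ll_new
          if (it <= cfg$mcmc_burnin) n_acc_burn <- n_acc_burn + 1L
          else n_acc <- n_acc + 1L
        }
      }
      if (it == cfg$mcmc_burnin && n_acc_burn == 0L && cfg$mcmc_burnin > 0L)
        eb_warning("eb_model_warning", sprintf(
          "subtype %d: no MCMC proposals accepted during burn-in (possible likelihood pathology)",
          k))
      if (it > cfg$mcmc_burnin)
        counts[cbind(seq_len(M), z)] <- counts[cbind(seq_len(M), z)] + 1
    }
    Ps[[k]] <- counts / cfg$mcmc_final
    acc_rates[k] <- n_acc / cfg$mcmc_final
  }
  structure(list(P = Ps, accept_rate = acc_rates), class = "eb_confidence")
}

#' Maximum a posteriori subject assignments
#'
#' Reports, per subject, the MAP subtype and stage with ties broken toward
#' the lower stage and then the lower subtype index. Internal stage 0 (no
#' events yet) is reported as stage 1, so reported stages run 1..S.
#'
#' @param model An `eb_model`.
#' @return A data.frame with columns `SubjectID`, `Outcome`, `Subtype`,
#'   `Stage`, `PosteriorProb`.
#' @export
assign_subjects <- function(model) {
  r <- model$posterior
  n <- dim(r)[1L]; K <- dim(r)[2L]; S1 <- dim(r)[3L]
  subtype <- integer(n); stage <- integer(n); prob <- numeric(n)
  for (i in seq_len(n)) {
    m <- matrix(r[i, , ], K, S1)
    best <- max(m)
    hits <- which(m >= best - 1e-12, arr.ind = TRUE)
    pick <- hits[order(hits[, 2L], hits[, 1L])[1L], ]
    subtype[i] <- pick[1L]
    stage[i] <- max(pick[2L] - 1L, 1L)  # stage 0 reported as stage 1
    prob[i] <- best
  }
  data.frame(SubjectID = model$cohort$meta$SubjectID,
             Outcome = model$cohort$meta$Outcome,
             Subtype = subtype, Stage = stage, PosteriorProb = prob,
             stringsAsFactors = FALSE)
}

#' Restrict a cohort to a feature subset
#'
#' @param cohort An `eb_cohort`.
#' @param features Character vector of feature names to keep (order kept).
#' @return The restricted `eb_cohort`.
#' @export
subset_cohort <- function(cohort, features) {
  missing <- setdiff(features, colnames(cohort$X))
  if (length(missing))
    eb_abort("eb_config_error", paste0(
      "features not present in the cohort: ",
      paste(utils::head(missing, 5L), collapse = ", ")))
  cohort$X <- cohort$X[, features, drop = FALSE]
  cohort
}
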