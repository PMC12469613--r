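# Shared fixtures, all generated in code.

# Small staged cohort as an eb_cohort (no files).
make_cohort <- function(n = 120, p = 30, K = 1, S = 4,
                        scheme = "ordered_three_class", effect = 5,
                        noise = 1, seed = 1, props = NULL,
                        missing_rate = 0) {
  spec <- generator_spec(n_subjects = n, n_features = p, n_informative = p,
                         n_subtypes = K, n_stages = S, effect_size = effect,
                         noise_sd = noise, outcome_scheme = scheme,
                         outcome_props = props, missing_rate = missing_rate,
                         seed = seed)
  g <- generate_cohort(spec)
  X <- as.matrix(g$data[, -1])
  rownames(X) <- g$data$SubjectID
  cohort <- new_cohort(X, g$meta, outcome_order = g$outcome_order,
                       baseline = g$baseline)
  list(cohort = cohort, truth = g$truth, gen = g)
}

# Write a small delimited table for readiness tests.
write_table_file <- function(df, path, sep) {
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# Best subtype-assignment accuracy over label permutations (K = 2).
subtype_accuracy2 <- function(assigned, truth) {
  tab <- table(factor(assigned, 1:2), factor(truth, 1:2))
  max(sum(diag(tab)), tab[1, 2] + tab[2, 1]) / sum(tab)
}

# All ordered partitions of M items into S contiguous clusters of size >=
# min_size, returned as cluster-assignment vectors over a fixed ordering.
enumerate_partitions <- function(ordering, S, min_size) {
  M <- length(ordering)
  out <- list()
  compose <- function(remaining, parts) {
    if (length(parts) == S - 1L) {
      last <- remaining
      if (last >= min_size) out[[length(out) + 1L]] <<- c(parts, last)
      return(invisible())
    }
    slots_left <- S - length(parts) - 1L
    for (s in min_size:(remaining - min_size * slots_left)) {
      if (remaining - s >= min_size * slots_left) compose(remaining - s, c(parts, s))
    }
  }
  compose(M, integer(0))
  lapply(out, function(sizes) {
    z <- integer(M)
    z[ordering] <- rep.int(seq_len(S), sizes)
    z
  })
}

# Every ordering (permutation) of M items; M must be tiny.
all_orderings <- function(M) {
  if (M == 1L) return(list(1L))
  out <- list()
  for (perm in all_orderings(M - 1L)) {
    for (pos in seq_len(M)) {
      out[[length(out) + 1L]] <- append(perm, M, after = pos - 1L)
    }
  }
  out
}
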