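# Random-graph benchmark: generate original/augmented network pairs under
# standard random-graph models and score the heuristic strategies against
# the exact reference classification.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. All simulation randomness flows through this helper so
# any replicate is reproducible in isolation.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Counter-based seed stream: one root seed, a replicate counter and a small
# salt (model / purpose) give an independent, reproducible sub-seed < 2^31.
derive_seed <- function(seed, replicate, salt = 0L) {
  ((as.double(seed) %% 50021) * 40013 + as.double(replicate) * 2017 +
     as.double(salt) * 131071) %% 2147483629 + 1
}

model_salt <- c(er = 1L, ba = 2L, ws = 3L)

#' Generate a random original/augmented network pair
#'
#' Draws one augmented network of `n_original + n_added` nodes under a
#' random-graph model, marks `n_added` nodes (chosen uniformly at random)
#' as added, and takes the original network as the subgraph induced on the
#' remaining nodes. This construction is model-agnostic and guarantees the
#' structure of a growing similarity network: every original node and every
#' original edge is present in the augmented network.
#'
#' Models and default parameters (all overridable via `model_params`):
#' * `"er"` — Erdős–Rényi G(n, p) with `p = 4/(n-1)` (mean degree ~4);
#' * `"ba"` — Barabási–Albert preferential attachment with `m = 2` edges
#'   per new node;
#' * `"ws"` — Watts–Strogatz ring lattice with `nei = 2` neighbours on
#'   each side (degree 4) and rewiring probability `p_rewire = 0.05`.
#'
#' @param model `"er"`, `"ba"` or `"ws"`.
#' @param n_original,n_added Node counts of the original network and of
#'   the added set.
#' @param model_params Optional list overriding `p`, `m`, `nei`,
#'   `p_rewire`.
#' @param replicate Replicate counter; together with `seed` it determines
#'   the networks completely.
#' @param seed Root seed.
#' @return An [augmented_pair()].
#' @examples
#' ap <- generate_pair("er", n_original = 20, n_added = 5, seed = 1)
#' length(ap$added)
#' @export
generate_pair <- function(model = c("er", "ba", "ws"), n_original = 100,
                          n_added = 100, model_params = list(),
                          replicate = 1, seed = 1) {
  model <- match.arg(model)
  stopifnot(n_original >= 2, n_added >= 1)
  n <- n_original + n_added
  mp <- model_params
  g <- with_seed(derive_seed(seed, replicate, model_salt[[model]]), {
    g <- switch(model,
      er = igraph::sample_gnp(n, p = if (is.null(mp$p)) 4 / (n - 1) else mp$p),
      ba = igraph::sample_pa(n, m = if (is.null(mp$m)) 2 else mp$m,
                             directed = FALSE),
      ws = igraph::simplify(igraph::sample_smallworld(
        1, n, nei = if (is.null(mp$nei)) 2 else mp$nei,
        p = if (is.null(mp$p_rewire)) 0.05 else mp$p_rewire)))
    igraph::V(g)$name <- sprintf(paste0("n%0", nchar(n), "d"), seq_len(n))
    added <- sample(igraph::V(g)$name, n_added)
    list(g = g, added = added)
  })
  x <- igraph::induced_subgraph(g$g, setdiff(igraph::V(g$g)$name, g$added))
  augmented_pair(x, g$g)
}

#' Score heuristic strategies against the exact reference
#'
#' Samples original node pairs (without replacement; all pairs when fewer
#' exist), classifies them with each requested strategy and with the exact
#' minimum-cost-flow reference, and reports the labels side by side.
#'
#' @param ap An [augmented_pair()].
#' @param params A [brides_params()].
#' @param pairs_sampled Number of original pairs to sample.
#' @param strategies Character vector of strategy names (see [brides()]).
#' @param seed Optional seed for the pair sampling (current RNG stream is
#'   used when `NULL`).
#' @return A data frame with columns `i`, `j`, `oracle`, one label column
#'   per strategy, and one logical `<strategy>_match` column per strategy.
#' @export
score_strategies <- function(ap, params = brides_params(),
                             pairs_sampled = 100,
                             strategies = c("brides", "brides_y",
                                            "brides_yc", "brides_ec"),
                             seed = NULL) {
  ap <- as_augmented_pair(ap)
  orig <- sort(igraph::V(ap$x)$name)
  all_pairs <- t(utils::combn(orig, 2L))
  take <- function() {
    if (nrow(all_pairs) <= pairs_sampled) all_pairs
    else all_pairs[sort(sample.int(nrow(all_pairs), pairs_sampled)), ,
                   drop = FALSE]
  }
  pairs <- if (is.null(seed)) take() else with_seed(seed, take())
  ref <- oracle_classify(ap, engine = "flow", params = params, pairs = pairs)
  out <- data.frame(i = pairs[, 1L], j = pairs[, 2L],
                    oracle = ref$records$label, stringsAsFactors = FALSE)
  for (s in strategies) {
    lab <- brides(ap, strategy = s, params = params, pairs = pairs)$records$label
    out[[s]] <- lab
    out[[paste0(s, "_match")]] <- lab == out$oracle
  }
  out
}

#' Accuracy benchmark over a grid of random-graph configurations
#'
#' Reproduces the accuracy experiment: for each combination of random-graph
#' model and number of added nodes, generates `replicates` independent
#' original/augmented pairs, classifies a sample of original node pairs
#' with each strategy, and reports the percentage of labels agreeing with
#' the exact reference, averaged over replicates. Wall-clock time per
#' strategy is recorded for information only; it is hardware-dependent and
#' never asserted.
#'
#' @param models Subset of `c("er", "ba", "ws")`.
#' @param n_added Integer vector of added-node counts.
#' @param n_original Original network size.
#' @param replicates Replicates per (model, n_added) cell.
#' @param pairs_sampled Original pairs scored per replicate.
#' @param strategies Strategies to score (see [brides()]).
#' @param params A [brides_params()].
#' @param model_params Passed to [generate_pair()].
#' @param seed Root seed; the full grid is a deterministic function of it.
#' @return A data frame with columns `model`, `n_added`, `strategy`,
#'   `accuracy` (percent), `mean_runtime_s`, `replicates`, `seed`.
#' @export
run_experiment <- function(models = c("er", "ba", "ws"),
                           n_added = c(5, 25, 50, 100), n_original = 100,
                           replicates = 1000, pairs_sampled = 100,
                           strategies = c("brides", "brides_y",
                                          "brides_yc", "brides_ec"),
                           params = brides_params(), model_params = list(),
                           seed = 1) {
  models <- match.arg(models, several.ok = TRUE)
  rows <- list()
  for (model in models) {
    for (na in n_added) {
      acc <- matrix(NA_real_, nrow = replicates, ncol = length(strategies),
                    dimnames = list(NULL, strategies))
      rt <- matrix(0, nrow = replicates, ncol = length(strategies),
                   dimnames = list(NULL, strategies))
      for (rep_i in seq_len(replicates)) {
        ap <- generate_pair(model, n_original = n_original, n_added = na,
                            model_params = model_params,
                            replicate = rep_i, seed = seed)
        orig <- sort(igraph::V(ap$x)$name)
        all_pairs <- t(utils::combn(orig, 2L))
        pairs <- with_seed(derive_seed(seed, rep_i, 7L + model_salt[[model]]), {
          if (nrow(all_pairs) <= pairs_sampled) all_pairs
          else all_pairs[sort(sample.int(nrow(all_pairs), pairs_sampled)), ,
                         drop = FALSE]
        })
        ref <- oracle_classify(ap, engine = "flow", params = params,
                               pairs = pairs)$records$label
        for (s in strategies) {
          t0 <- proc.time()[["elapsed"]]
          lab <- brides(ap, strategy = s, params = params,
                        pairs = pairs)$records$label
          rt[rep_i, s] <- proc.time()[["elapsed"]] - t0
          acc[rep_i, s] <- 100 * mean(lab == ref)
        }
      }
      for (s in strategies) {
        rows[[length(rows) + 1L]] <- data.frame(
          model = model, n_added = na, strategy = s,
          accuracy = mean(acc[, s]), mean_runtime_s = mean(rt[, s]),
          replicates = replicates, seed = seed, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
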