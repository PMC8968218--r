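# Bayesian structure learning: MCMC samplers over DAG space and the
# exact dynamic-programming oracle used to validate them.

log_zeta <- function(tab, nbits) {
  if (nbits == 0) return(tab)
  for (b in 0:(nbits - 1)) {
    bit <- bitwShiftL(1L, b)
    idx <- which(bitwAnd(seq_along(tab) - 1L, bit) != 0L)
    tab[idx] <- logaddexp(tab[idx], tab[idx - bit])
  }
  tab
}

decompress_mask_r <- function(comp, j) {
  lowbits <- bitwShiftL(1L, j - 1L) - 1L
  low <- bitwAnd(comp, lowbits)
  low + (comp - low) * 2L
}

#' Sample DAGs from the structure posterior by MCMC
#'
#' Two samplers target the same posterior (proportional to
#' `exp(sum of local scores)`, i.e. a uniform structure prior times any
#' per-edge penalty folded into the score tables):
#' \describe{
#'   \item{`edge_mh`}{Metropolis-Hastings over single-edge additions,
#'     deletions and reversals with acyclicity rejection and the
#'     proposal-count Hastings correction.}
#'   \item{`partition`}{moves on ordered node partitions (the layering
#'     of a DAG), marginalizing parent sets within blocks, followed by a
#'     DAG draw conditional on the partition.  Every DAG corresponds to
#'     exactly one layering, so the partition chain induces the same
#'     DAG posterior.}
#' }
#'
#' @param data gaussianized data matrix, or a prebuilt [bge_score_tables]
#'   object.
#' @param iterations total MCMC iterations (the full-scale preset is
#'   1e7 iterations retaining 50,000 DAGs; tests use far fewer).
#' @param burn_in iterations discarded (default 20% of `iterations`).
#' @param thinning spacing between retained samples (default chosen to
#'   retain at most 50,000 DAGs).
#' @param config a [score_config] (ignored when `data` is a cache).
#' @param seed integer seed.
#' @param sampler `"partition"` (default) or `"edge_mh"`.
#' @return an object of class `dag_sample_set`: `parent_masks` (integer
#'   matrix, one row per retained DAG, column `j` the bitmask of node
#'   `j`'s parents), `labels`, `score_trace`, `acceptance_rate`, and the
#'   run metadata.
#' @export
sample_dags <- function(data, iterations = 2e5, burn_in = NULL,
                        thinning = NULL, config = score_config(),
                        seed = NULL, sampler = c("partition", "edge_mh")) {
  sampler <- match.arg(sampler)
  tb <- if (inherits(data, "bge_score")) data else bge_score_tables(data, config)
  if (is.null(burn_in)) burn_in <- floor(0.2 * iterations)
  if (is.null(thinning))
    thinning <- max(1, floor((iterations - burn_in) / 50000))
  stopifnot(thinning >= 1, burn_in >= 0, iterations > burn_in)
  p <- tb$p
  res <- if (sampler == "edge_mh") {
    with_seed(seed, cpp_edge_mh(tb$tables, p, iterations, burn_in, thinning,
                                0.0, integer(0)))
  } else {
    run_partition_mcmc(tb, iterations, burn_in, thinning, seed)
  }
  masks <- res$parent_masks
  colnames(masks) <- tb$labels
  structure(list(parent_masks = masks, labels = tb$labels, p = p,
                 iterations = iterations, burn_in = burn_in,
                 thinning = thinning, seed = seed, sampler = sampler,
                 score_trace = as.numeric(res$score_trace),
                 acceptance_rate = res$acceptance_rate,
                 am = tb$am, aw = tb$aw, edge_logprior = tb$edge_logprior),
            class = "dag_sample_set")
}

#' @export
print.dag_sample_set <- function(x, ...) {
  cat(sprintf("<dag_sample_set> %d DAGs over %d nodes (%s sampler, %g iterations, acceptance %.3f)\n",
              nrow(x$parent_masks), x$p, x$sampler, x$iterations,
              x$acceptance_rate))
  invisible(x)
}

# partition score: sum over nodes of the log marginal score of all
# parent sets drawn from earlier blocks with at least one parent in the
# immediately preceding block; vectorized over nodes via matrix lookups
partition_log_score <- function(tbm, ztm, pow2, nodes, blk, k) {
  bm <- integer(k)
  msk <- pow2[nodes]
  for (i in seq_len(k)) bm[i] <- sum(msk[blk == i])
  Pmask <- c(0L, cumsum(bm))[seq_len(k)]      # union of earlier blocks
  Qmask <- c(0L, bm)[seq_len(k)]              # immediately preceding block
  Pv <- Pmask[blk]; Qv <- Qmask[blk]
  pj <- pow2[nodes]
  lowP <- Pv %% pj
  iP <- lowP + (Pv %/% (2 * pj)) * pj
  Bv <- Pv - Qv                               # blocks are disjoint
  lowB <- Bv %% pj
  iB <- lowB + (Bv %/% (2 * pj)) * pj
  a <- ztm[iP + 1L + (nodes - 1L) * nrow(ztm)]
  b <- ztm[iB + 1L + (nodes - 1L) * nrow(ztm)]
  h <- a + log1p(-exp(b - a))
  first <- blk == 1L
  if (any(first)) h[first] <- tbm[1L, nodes[first]]
  sum(h)
}

run_partition_mcmc <- function(tb, iterations, burn_in, thinning, seed) {
  p <- tb$p
  zt <- lapply(tb$tables, function(tab) log_zeta(tab, p - 1L))
  tbm <- do.call(cbind, tb$tables)            # 2^(p-1) x p score matrix
  ztm <- do.call(cbind, zt)
  pow2 <- bitwShiftL(1L, 0:(p - 1))
  nodes <- seq_len(p)
  keep <- floor((iterations - burn_in) / thinning)
  masks_out <- matrix(0L, keep, p)
  trace <- numeric(keep)
  with_seed(seed, {
    blk <- rep(1L, p)      # one block: the empty DAG's layering
    k <- 1L
    cur <- partition_log_score(tbm, ztm, pow2, nodes, blk, k)
    stored <- 0L
    accepted <- 0L; proposed <- 0L
    for (it in seq_len(iterations)) {
      if (p >= 2) {
        if (runif(1) < 0.9) {
          # remove one node, re-insert uniformly over the 2k'+1 slots
          v <- floor(runif(1) * p) + 1L
          vb <- blk[v]
          singleton <- sum(blk == vb) == 1L
          rb <- blk
          rk <- k
          if (singleton) {
            rb[rb > vb] <- rb[rb > vb] - 1L
            rk <- k - 1L
          }
          slot <- floor(runif(1) * (2L * rk + 1L)) + 1L
          nb <- rb
          if (slot <= rk) {        # join existing block `slot`
            nb[v] <- slot
            nk <- rk
          } else {                 # new singleton block after gap g
            g <- slot - rk - 1L    # 0..rk
            nb[nb > g] <- nb[nb > g] + 1L
            nb[v] <- g + 1L
            nk <- rk + 1L
          }
          proposed <- proposed + 1L
          prop <- partition_log_score(tbm, ztm, pow2, nodes, nb, nk)
          if (is.finite(prop) && log(runif(1)) < prop - cur) {
            blk <- nb; k <- nk; cur <- prop
            accepted <- accepted + 1L
          }
        } else {
          # swap the blocks of two nodes
          v1 <- floor(runif(1) * p) + 1L
          v2 <- floor(runif(1) * (p - 1L)) + 1L
          if (v2 >= v1) v2 <- v2 + 1L
          vs <- c(v1, v2)
          if (blk[vs[1]] != blk[vs[2]]) {
            proposed <- proposed + 1L
            nb <- blk
            nb[vs] <- blk[rev(vs)]
            prop <- partition_log_score(tbm, ztm, pow2, nodes, nb, k)
            if (is.finite(prop) && log(runif(1)) < prop - cur) {
              blk <- nb; cur <- prop
              accepted <- accepted + 1L
            }
          }
        }
      }
      if (it > burn_in && (it - burn_in) %% thinning == 0 && stored < keep) {
        stored <- stored + 1L
        pm <- integer(p)
        bm <- integer(k)
        for (i in seq_len(k)) bm[i] <- sum(pow2[blk == i])
        Pmask <- c(0L, cumsum(bm))
        for (j in which(blk > 1L)) {
          i <- blk[j]
          pj <- pow2[j]
          P <- Pmask[i]; Q <- bm[i - 1L]
          lowP <- P %% pj; lowQ <- Q %% pj
          cmask <- cpp_sample_parent_set(tbm[, j],
                                         lowP + (P %/% (2L * pj)) * pj,
                                         lowQ + (Q %/% (2L * pj)) * pj)
          low <- cmask %% pj
          pm[j] <- low + (cmask - low) * 2L
        }
        masks_out[stored, ] <- pm
        lowv <- pm %% pow2
        trace[stored] <- sum(tbm[lowv + (pm - lowv) %/% 2L + 1L +
                                   (nodes - 1L) * nrow(tbm)])
      }
    }
    list(parent_masks = masks_out, score_trace = trace,
         acceptance_rate = if (proposed > 0) accepted / proposed else 0)
  })
}

#' Exact posterior edge probabilities by dynamic programming
#'
#' Sums the structure score over every DAG exactly once (inclusion-
#' exclusion over sink sets) to obtain the evidence and each directed
#' edge's posterior probability under the same uniform structure prior
#' the samplers target.  Intended as a small-graph oracle.
#'
#' @param data gaussianized data matrix or a [bge_score_tables] cache.
#' @param config a [score_config].
#' @param max_p refusal bound on the number of nodes (default 14).
#' @return list with `edge_prob` (`p x p`, `[i, j] = P(i -> j)`, zero
#'   diagonal) and `log_evidence`.
#' @export
exact_edge_posterior <- function(data, config = score_config(), max_p = 14) {
  tb <- if (inherits(data, "bge_score")) data else bge_score_tables(data, config)
  if (tb$p > max_p)
    stop(sprintf("exact posterior is exponential in p; refusing p = %d > %d (use sample_dags instead)",
                 tb$p, max_p))
  res <- cpp_exact_posterior(tb$tables, tb$p)
  dimnames(res$edge_prob) <- list(tb$labels, tb$labels)
  res
}

#' Directed-edge inclusion frequencies of a DAG sample
#'
#' @param set a `dag_sample_set`.
#' @return `p x p` matrix, `[i, j]` the fraction of sampled DAGs
#'   containing the edge `i -> j`.
#' @export
edge_inclusion_matrix <- function(set) {
  stopifnot(inherits(set, "dag_sample_set"))
  p <- set$p
  out <- matrix(0, p, p, dimnames = list(set$labels, set$labels))
  for (j in seq_len(p)) {
    col <- set$parent_masks[, j]
    for (i in seq_len(p)) {
      if (i == j) next
      out[i, j] <- mean(bitwAnd(col, bitwShiftL(1L, i - 1L)) != 0L)
    }
  }
  out
}

#' Compare two independent chains
#'
#' Reports the maximum absolute difference in per-edge inclusion
#' frequencies between two chains run on the same data and settings,
#' together with score-trace summaries and acceptance rates; flags the
#' pair when the discrepancy exceeds `tol` (default 0.05).  Chains with
#' mismatched settings are refused.
#'
#' @param set,second_chain two `dag_sample_set` objects.
#' @param tol discrepancy threshold for the convergence flag.
#' @return list with `max_edge_discrepancy`, `flagged`, per-chain
#'   `acceptance_rates` and `score_summary`.
#' @export
convergence_diagnostics <- function(set, second_chain, tol = 0.05) {
  stopifnot(inherits(set, "dag_sample_set"),
            inherits(second_chain, "dag_sample_set"))
  same <- identical(set$labels, second_chain$labels) &&
    set$iterations == second_chain$iterations &&
    set$thinning == second_chain$thinning &&
    set$burn_in == second_chain$burn_in &&
    set$sampler == second_chain$sampler &&
    set$am == second_chain$am && set$aw == second_chain$aw &&
    set$edge_logprior == second_chain$edge_logprior
  if (!same) stop("chains were run with different settings: comparison refused")
  d <- max(abs(edge_inclusion_matrix(set) -
                 edge_inclusion_matrix(second_chain)))
  list(max_edge_discrepancy = d, flagged = d > tol,
       acceptance_rates = c(set$acceptance_rate,
                            second_chain$acceptance_rate),
       score_summary = rbind(chain1 = summary(set$score_trace),
                             chain2 = summary(second_chain$score_trace)))
}

#' Persist a DAG sample set as plain text
#'
#' One line per retained DAG: the sorted `parent>child` pairs joined by
#' commas (empty line for the empty DAG), preceded by two header lines
#' (`#meta` JSON metadata and `#scores` the score trace).  The reader
#' round-trips bit-exactly.
#'
#' @param set a `dag_sample_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dag_samples <- function(set, path) {
  stopifnot(inherits(set, "dag_sample_set"))
  meta <- set[c("labels", "p", "iterations", "burn_in", "thinning",
                "seed", "sampler", "acceptance_rate", "am", "aw",
                "edge_logprior")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#meta ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                               digits = NA, null = "null")),
             con)
  writeLines(paste0("#scores ",
                    paste(sprintf("%.17g", set$score_trace), collapse = ",")),
             con)
  lines <- apply(set$parent_masks, 1, function(pm) {
    pairs <- character(0)
    for (j in seq_len(set$p)) {
      for (i in mask_nodes(pm[j], set$p))
        pairs <- c(pairs, paste0(set$labels[i], ">", set$labels[j]))
    }
    paste(sort(pairs), collapse = ",")
  })
  writeLines(lines, con)
  invisible(path)
}

#' Read a DAG sample set written by [write_dag_samples]
#' @param path the file path.
#' @return a `dag_sample_set`.
#' @export
read_dag_samples <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#meta ") || !startsWith(lines[2], "#scores "))
    stop("not a DAG sample file")
  meta <- jsonlite::fromJSON(sub("^#meta ", "", lines[1]))
  scores <- sub("^#scores ", "", lines[2])
  scores <- if (nzchar(scores)) as.numeric(strsplit(scores, ",")[[1]]) else numeric(0)
  body <- lines[-(1:2)]
  p <- meta$p
  labels <- meta$labels
  masks <- matrix(0L, length(body), p)
  colnames(masks) <- labels
  for (r in seq_along(body)) {
    if (!nzchar(body[r])) next
    for (pair in strsplit(body[r], ",", fixed = TRUE)[[1]]) {
      ends <- strsplit(pair, ">", fixed = TRUE)[[1]]
      i <- match(ends[1], labels); j <- match(ends[2], labels)
      masks[r, j] <- bitwOr(masks[r, j], bitwShiftL(1L, i - 1L))
    }
  }
  structure(list(parent_masks = masks, labels = labels, p = p,
                 iterations = meta$iterations, burn_in = meta$burn_in,
                 thinning = meta$thinning, seed = meta$seed,
                 sampler = meta$sampler, score_trace = scores,
                 acceptance_rate = meta$acceptance_rate,
                 am = meta$am, aw = meta$aw,
                 edge_logprior = meta$edge_logprior),
            class = "dag_sample_set")
}
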