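ARD_PAIRS <- {
  p <- expand.grid(from = 1:4, to = 1:4)
  p <- p[p$from != p$to, ]
  p[order(p$from, p$to), ]
}
ARD_RATE_NAMES <- sprintf("q%d%d", ARD_PAIRS$from, ARD_PAIRS$to)

ard_q <- function(rates) {
  Q <- matrix(0, 4, 4, dimnames = list(FOUR_STATE_LETTERS, FOUR_STATE_LETTERS))
  for (i in seq_len(nrow(ARD_PAIRS))) {
    Q[ARD_PAIRS$from[i], ARD_PAIRS$to[i]] <- rates[i]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

as_state_int <- function(states) {
  if (is.character(states)) {
    out <- match(states, FOUR_STATE_LETTERS)
    if (anyNA(out)) stop("states must be letters A-D or integers 1-4")
    return(setNames(out, names(states)))
  }
  if (!all(states %in% 1:4)) stop("states must be letters A-D or integers 1-4")
  as.integer(states) |> setNames(names(states))
}

## log P(all tips in state s) for each s, used by the Lewis correction
constant_state_logliks <- function(ps, Q, rp) {
  vapply(1:4, function(s) {
    tp <- matrix(0, nrow(ps$tp), 4)
    tp[, s] <- 1
    ctmc_loglik_cpp(ps$edge, ps$edge_length, tp, ps$n_node_total, Q,
                    rp$mode, rp$vec)
  }, 0)
}

ard_loglik <- function(ps, rates, rp, lewis = TRUE) {
  Q <- ard_q(rates)
  ll <- ctmc_loglik_cpp(ps$edge, ps$edge_length, ps$tp, ps$n_node_total, Q,
                        rp$mode, rp$vec)
  if (!is.finite(ll)) return(-Inf)
  if (lewis) {
    const <- constant_state_logliks(ps, Q, rp)
    p_const <- exp(logsumexp(const))
    if (p_const >= 1 - 1e-12) return(-Inf)
    ll <- ll - log1p(-p_const)
  }
  ll
}

#' Fit a 4-state all-rates-different Markov model by maximum likelihood
#'
#' All 12 ordered-pair transition rates among the combined states A=(0,0),
#' B=(0,1), C=(1,0), D=(1,1) are free (unlike the co-evolution model, dual
#' transitions are allowed here). The likelihood uses FitzJohn root
#' probabilities (each root state weighted by its own normalized partial
#' likelihood) and, by default, the Lewis ascertainment correction for
#' variable characters: `L_corr = L / (1 - sum_s L(all tips in state s))`.
#' Optimization runs on log rates with box bounds, from several random
#' starts, and keeps the best optimum.
#'
#' @param tree a `phylo` object.
#' @param states tip states as letters A-D or integers 1-4, named by taxon.
#' @param n_starts number of random optimizer starts (default 5).
#' @param seed seed for the random starts.
#' @param lewis apply the Lewis correction (default TRUE).
#' @param lower,upper box bounds on the rates.
#' @return an `ard_model`: named `rates` (12), `loglik`, `root_prior`,
#'   `lewis`, `convergence` info.
#' @export
fit_ard <- function(tree, states, n_starts = 5, seed = 1, lewis = TRUE,
                    lower = 1e-9, upper = 100) {
  states <- as_state_int(states)
  if (is.null(names(states))) stop("states must be named by taxon")
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing)) stop(sprintf("no state for tips: %s",
                                    paste(head(missing, 5), collapse = ", ")))
  n_obs <- length(unique(states))
  if (n_obs < 4) {
    warning(sprintf("only %d of 4 states observed at the tips", n_obs))
  }
  tp <- matrix(0, length(tree$tip.label), 4,
               dimnames = list(tree$tip.label, FOUR_STATE_LETTERS))
  tp[cbind(seq_len(nrow(tp)), states[tree$tip.label])] <- 1
  ps <- prune_structure(tree, tree$tip.label)
  ps$tp <- tp[ps$tree$tip.label, , drop = FALSE]
  rp <- root_mode_code("fitzjohn")

  obj <- function(lr) -ard_loglik(ps, exp(lr), rp, lewis)
  fits <- with_seed(seed, {
    lapply(seq_len(n_starts), function(s) {
      start <- log(pmin(pmax(rgamma(12, 1, 1), lower * 10), upper / 10))
      tryCatch(
        nlminb(start, obj, lower = log(lower), upper = log(upper),
               control = list(iter.max = 500, eval.max = 2000)),
        error = function(e) NULL
      )
    })
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$objective), fits)
  if (!length(fits)) stop("optimizer failed to converge from every start")
  best <- fits[[which.min(vapply(fits, `[[`, 0, "objective"))]]
  structure(
    list(rates = setNames(exp(best$par), ARD_RATE_NAMES),
         loglik = -best$objective, root_prior = "fitzjohn", lewis = lewis,
         convergence = best$convergence, n_starts_ok = length(fits)),
    class = "ard_model"
  )
}

#' @export
print.ard_model <- function(x, ...) {
  cat(sprintf("ard_model: logLik %.3f (%s Lewis correction), 12 free rates\n",
              x$loglik, if (x$lewis) "with" else "without"))
  invisible(x)
}

#' Marginal ancestral state reconstruction under a fitted ARD model
#'
#' Exact per-node marginal posterior state probabilities given the MLE
#' rates: a rescaled Felsenstein down-pass is combined with an up-pass
#' carrying the likelihood of everything outside each node's subtree, with
#' the FitzJohn root distribution. The Lewis variable-sites correction is a
#' constant in the node states and therefore cancels from the marginals.
#'
#' @param tree a `phylo` object.
#' @param states tip states (letters A-D or integers 1-4, named by taxon).
#' @param model an `ard_model` from [fit_ard()], or a named 12-vector of
#'   rates.
#' @return an `asr_result`: matrix `node_probs` ((Nnode) x 4, rows named by
#'   internal node id) summing to 1 per row, plus `rates`, `loglik` and the
#'   root distribution used.
#' @export
marginal_reconstruction <- function(tree, states, model) {
  rates <- if (inherits(model, "ard_model")) model$rates else model
  if (length(rates) != 12) stop("model must supply 12 ARD rates (is it fitted?)")
  states <- as_state_int(states)
  Q <- ard_q(rates)
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  root <- tree$edge[nrow(tree$edge), 1]

  down <- matrix(1, n_all, 4)  # rescaled partials, tips then internals
  down[seq_len(n_tip), ] <- 0
  down[cbind(seq_len(n_tip), states[tree$tip.label])] <- 1
  P_edge <- vector("list", nrow(tree$edge))
  msg_up <- matrix(NA_real_, n_all, 4)  # message child -> parent per node
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    d <- down[ch, ]
    s <- sum(d)
    if (s <= 0) stop("impossible tip configuration")
    d <- d / s
    down[ch, ] <- d
    P_edge[[e]] <- transition_matrix(Q, tree$edge.length[e])
    m <- drop(P_edge[[e]] %*% d)
    msg_up[ch, ] <- m
    down[p, ] <- down[p, ] * m
  }

  root_w <- down[root, ] / sum(down[root, ])  # FitzJohn weights

  ## up-pass: above[j] = likelihood of data outside j's subtree, per state;
  ## sibling products are formed explicitly (no division, safe with zeros)
  above <- matrix(NA_real_, n_all, 4)
  above[root, ] <- root_w
  edges_by_parent <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  for (e in rev(seq_len(nrow(tree$edge)))) {  # preorder
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sib_prod <- above[p, ]
    for (e2 in edges_by_parent[[as.character(p)]]) {
      if (e2 != e) sib_prod <- sib_prod * msg_up[tree$edge[e2, 2], ]
    }
    a <- drop(t(P_edge[[e]]) %*% sib_prod)
    s <- sum(a)
    above[ch, ] <- if (s > 0) a / s else a
  }

  nodes <- (n_tip + 1L):n_all
  probs <- down[nodes, , drop = FALSE] * above[nodes, , drop = FALSE]
  probs <- probs / rowSums(probs)
  dimnames(probs) <- list(nodes, FOUR_STATE_LETTERS)
  structure(
    list(node_probs = probs, rates = rates,
         loglik = if (inherits(model, "ard_model")) model$loglik else NA_real_,
         root_distribution = setNames(root_w, FOUR_STATE_LETTERS)),
    class = "asr_result"
  )
}

#' @export
print.asr_result <- function(x, ...) {
  cat(sprintf("asr_result: %d internal nodes; root marginal: %s\n",
              nrow(x$node_probs),
              paste(sprintf("%s=%.2f", FOUR_STATE_LETTERS,
                            x$node_probs[1, ]), collapse = " ")))
  invisible(x)
}

#' Write ancestral state probabilities as TSV
#' @param asr an `asr_result`.
#' @param path output path.
#' @export
write_asr <- function(asr, path) {
  df <- data.frame(node_id = rownames(asr$node_probs), asr$node_probs,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}
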