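DEP_RATE_NAMES <- c("q12", "q13", "q21", "q24", "q31", "q34", "q42", "q43")
INDEP_RATE_NAMES <- c("alpha1", "beta1", "alpha2", "beta2")

#' Rate model for paired binary trait evolution
#'
#' Two continuous-time Markov models over the four combined states
#' 1=(0,0), 2=(0,1), 3=(1,0), 4=(1,1). The dependent model has eight free
#' rates (transition rates of each trait depend on the state of the other);
#' the independent model has four (gain/loss per trait) and maps onto the
#' dependent parameterization as q13=q24=alpha1, q31=q42=beta1,
#' q12=q34=alpha2, q21=q43=beta2. Simultaneous changes of both traits
#' (1<->4, 2<->3) are forbidden in both models.
#'
#' @param kind `"dependent"` or `"independent"`.
#' @param rates named positive vector: for dependent, `q12,q13,q21,q24,q31,
#'   q34,q42,q43`; for independent, `alpha1,beta1,alpha2,beta2`. Unnamed
#'   vectors of the right length are accepted in that order.
#' @return a `rate_model` object.
#' @export
rate_model <- function(kind = c("dependent", "independent"), rates) {
  kind <- match.arg(kind)
  want <- if (kind == "dependent") DEP_RATE_NAMES else INDEP_RATE_NAMES
  if (is.null(names(rates))) {
    if (length(rates) != length(want)) {
      stop(sprintf("%s model needs %d rates", kind, length(want)))
    }
    names(rates) <- want
  }
  if (!setequal(names(rates), want)) {
    stop(sprintf("%s model needs rates named %s", kind,
                 paste(want, collapse = ", ")))
  }
  rates <- rates[want]
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("all rates must be positive and finite")
  }
  structure(list(kind = kind, rates = rates), class = "rate_model")
}

#' Map an independent rate model onto the 8-rate dependent parameterization
#' @param model a `rate_model`.
#' @return named vector of the 8 dependent-model rates.
#' @export
as_dependent_rates <- function(model) {
  stopifnot(inherits(model, "rate_model"))
  if (model$kind == "dependent") return(model$rates)
  r <- model$rates
  c(q12 = unname(r["alpha2"]), q13 = unname(r["alpha1"]),
    q21 = unname(r["beta2"]), q24 = unname(r["alpha1"]),
    q31 = unname(r["beta1"]), q34 = unname(r["alpha2"]),
    q42 = unname(r["beta1"]), q43 = unname(r["beta2"]))
}

#' Build the 4x4 generator matrix of a rate model
#'
#' Off-diagonal entries hold the transition rates between combined states;
#' the forbidden dual transitions (1<->4, 2<->3) are structurally zero and
#' each diagonal entry is minus its row sum.
#'
#' @param model a `rate_model`, or a named vector of the 8 dependent rates.
#' @return a 4x4 generator matrix with zero row sums.
#' @export
build_q <- function(model) {
  r <- if (inherits(model, "rate_model")) as_dependent_rates(model) else model
  if (!setequal(names(r), DEP_RATE_NAMES)) {
    stop("need the 8 dependent-model rates")
  }
  if (any(r <= 0)) stop("all rates must be positive")
  Q <- matrix(0, 4, 4, dimnames = list(1:4, 1:4))
  Q[1, 2] <- r[["q12"]]; Q[1, 3] <- r[["q13"]]
  Q[2, 1] <- r[["q21"]]; Q[2, 4] <- r[["q24"]]
  Q[3, 1] <- r[["q31"]]; Q[3, 4] <- r[["q34"]]
  Q[4, 2] <- r[["q42"]]; Q[4, 3] <- r[["q43"]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probability matrix over a branch
#'
#' @param Q a generator matrix (rows sum to 0, off-diagonals >= 0).
#' @param t branch length (>= 0).
#' @return the stochastic matrix `expm(Q t)`.
#' @export
transition_matrix <- function(Q, t) {
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0) {
    stop("branch length t must be a single non-negative number")
  }
  P <- as.matrix(Matrix::expm(Q * t))
  P[P < 0] <- 0
  P[P > 1] <- 1
  dimnames(P) <- dimnames(Q)
  P
}

#' Tip partial-likelihood vectors with ambiguity coding
#'
#' A fully observed tip has a single 1 at its state; a tip missing one of
#' the two traits has 1s at both compatible states; a fully missing tip is
#' all 1s.
#'
#' @param x,y binary vectors per taxon, possibly with NA.
#' @param taxa taxon names (rownames of the result).
#' @return numeric matrix (n x 4) of 0/1 partials.
#' @export
tip_partials <- function(x, y, taxa = names(x)) {
  n <- length(x)
  stopifnot(length(y) == n)
  m <- matrix(0, n, 4, dimnames = list(taxa, FOUR_STATE_LETTERS))
  for (i in seq_len(n)) {
    xs <- if (is.na(x[i])) 0:1 else x[i]
    ys <- if (is.na(y[i])) 0:1 else y[i]
    for (xv in xs) for (yv in ys) m[i, 1L + 2L * xv + yv] <- 1
  }
  m
}

## precompute the postorder structures the C++ likelihood needs
prune_structure <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) {
    stop(sprintf("tree lacks taxa: %s",
                 paste(head(missing, 5), collapse = ", ")))
  }
  if (length(taxa) < length(tree$tip.label)) {
    tree <- ape::keep.tip(tree, taxa)
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  list(tree = tree, edge = tree$edge, edge_length = tree$edge.length,
       tip_index = match(tree$tip.label, taxa),
       n_node_total = length(tree$tip.label) + tree$Nnode)
}

root_mode_code <- function(root_prior) {
  if (is.character(root_prior)) {
    switch(match.arg(root_prior, c("uniform", "fitzjohn")),
           uniform = list(mode = 0L, vec = rep(0.25, 4)),
           fitzjohn = list(mode = 1L, vec = rep(0.25, 4)))
  } else {
    stopifnot(is.numeric(root_prior), length(root_prior) == 4,
              all(root_prior >= 0), sum(root_prior) > 0)
    list(mode = 2L, vec = root_prior / sum(root_prior))
  }
}

#' Felsenstein pruning log-likelihood of tip data under a CTMC
#'
#' Post-order pruning with per-node rescaling (safe for trees with
#' thousands of tips). Root handling: `"uniform"` averages the root partials
#' over the four states, `"fitzjohn"` weights each state by its own
#' normalized root partial likelihood, and a numeric vector fixes the root
#' distribution.
#'
#' @param tree a `phylo` object.
#' @param tips numeric matrix (taxa x 4) of tip partials with rownames
#'   covering every tree leaf (see [tip_partials()]).
#' @param Q generator matrix.
#' @param root_prior `"uniform"`, `"fitzjohn"`, or a length-4 vector.
#' @return the log-likelihood (may be `-Inf` for impossible data).
#' @export
pruning_loglik <- function(tree, tips, Q, root_prior = "uniform") {
  stopifnot(is.matrix(tips), ncol(tips) == 4)
  rp <- root_mode_code(root_prior)
  taxa <- rownames(tips)
  if (length(tree$tip.label) == 1 || is.null(tree$edge)) {
    ## single-tip tree: likelihood is the prior mass on compatible states
    v <- tips[tree$tip.label, ]
    w <- if (rp$mode == 1L) v / sum(v) else rp$vec
    return(log(sum(w * v)))
  }
  missing <- setdiff(tree$tip.label, taxa)
  if (length(missing)) {
    stop(sprintf("no tip data for: %s", paste(head(missing, 5), collapse = ", ")))
  }
  ps <- prune_structure(tree, intersect(taxa, tree$tip.label))
  tp <- tips[ps$tree$tip.label, , drop = FALSE]
  ll <- ctmc_loglik_cpp(ps$edge, ps$edge_length, tp, ps$n_node_total,
                        Q, rp$mode, rp$vec)
  if (identical(ll, -Inf)) warning("all-zero partial at the root")
  ll
}

#' Simulate paired-trait evolution along a tree
#'
#' Gillespie simulation: exponential waiting times with the current state's
#' total exit rate, jumps proportional to the off-diagonal rates.
#'
#' @param tree a `phylo` object.
#' @param Q generator matrix.
#' @param root_state integer state in 1..4 or a probability vector of
#'   length 4.
#' @param seed integer seed.
#' @return named integer vector of tip states (1..4); the simulated root
#'   state is attached as attribute `root_state`.
#' @export
simulate_evolution <- function(tree, Q, root_state = 1L, seed = 1) {
  k <- nrow(Q)
  with_seed(seed, {
    if (length(root_state) == k) {
      stopifnot(all(root_state >= 0), sum(root_state) > 0)
      root_state <- sample.int(k, 1, prob = root_state)
    }
    root_state <- as.integer(root_state)
    if (length(root_state) != 1 || root_state < 1 || root_state > k) {
      stop("invalid root state")
    }
    tree <- ape::reorder.phylo(tree, "cladewise")
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    states <- integer(n_tip + tree$Nnode)
    states[root] <- root_state
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
      s <- states[p]
      t_left <- tree$edge.length[e]
      repeat {
        rate <- -Q[s, s]
        if (rate <= 0) break
        wait <- rexp(1, rate)
        if (wait >= t_left) break
        t_left <- t_left - wait
        probs <- Q[s, ]; probs[s] <- 0
        s <- sample.int(k, 1, prob = probs)
      }
      states[c] <- s
    }
    structure(setNames(states[seq_len(n_tip)], tree$tip.label),
              root_state = root_state)
  })
}

#' Write a generator matrix as TSV for inspection
#' @param Q a 4x4 generator matrix.
#' @param path output path.
#' @export
write_q <- function(Q, path) {
  df <- data.frame(state = rownames(Q) %||% as.character(1:4), Q,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}
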