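#' Simulate a pure-birth (Yule) tree
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per unit time (default 1).
#' @param seed integer seed.
#' @param height optional total tree height to rescale to (keeps relative
#'   branch lengths); unset leaves the Yule time scale (expected height
#'   roughly `log(n)/birth_rate`).
#' @return an ultrametric `phylo` with tips labelled `lang0001`, ...
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = 1, height = NULL) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
  tree$tip.label <- sprintf("lang%04d", seq_len(n_tips))
  if (!is.null(height)) {
    h <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * (height / h)
  }
  tree
}

#' Simulate geography, macro-areas and families for a tree
#'
#' Tip coordinates arise from Brownian diffusion of (longitude, latitude)
#' along the branches (longitude wrapped into [-180, 180), latitude clipped
#' to [-85, 85]), so tips that are close in the tree end up close in space
#' on average. Macro-areas are a k-means partition of the tip locations;
#' families are the maximal clades whose stem crosses the age threshold
#' `family_depth` (measured back from the tips).
#'
#' @param tree a `phylo`.
#' @param diffusion degrees^2 of coordinate variance per unit branch length
#'   (default 200).
#' @param m_areas number of macro-areas (default 4).
#' @param family_depth age threshold defining families (default one third
#'   of tree height).
#' @param seed integer seed.
#' @param root_location `c(longitude, latitude)` of the root.
#' @return a metadata data.frame (`taxon`, `longitude`, `latitude`,
#'   `macroarea`, `family`).
#' @export
simulate_metadata <- function(tree, diffusion = 200, m_areas = 4,
                              family_depth = NULL, seed = 1,
                              root_location = c(0, 20)) {
  n_tip <- length(tree$tip.label)
  if (m_areas > n_tip) stop("m_areas cannot exceed the number of tips")
  tree_o <- ape::reorder.phylo(tree, "cladewise")
  n_all <- n_tip + tree_o$Nnode
  root <- n_tip + 1L
  depths <- ape::node.depth.edgelength(tree_o)
  H <- max(depths[seq_len(n_tip)])
  family_depth <- family_depth %||% (H / 3)

  with_seed(seed, {
    lon <- numeric(n_all); lat <- numeric(n_all)
    lon[root] <- root_location[1]; lat[root] <- root_location[2]
    for (e in seq_len(nrow(tree_o$edge))) {
      p <- tree_o$edge[e, 1]; ch <- tree_o$edge[e, 2]
      sdv <- sqrt(diffusion * tree_o$edge.length[e])
      lon[ch] <- lon[p] + rnorm(1, 0, sdv)
      lat[ch] <- lat[p] + rnorm(1, 0, sdv)
    }
    lon <- ((lon + 180) %% 360) - 180
    lat <- pmin(pmax(lat, -85), 85)
    tip_lon <- lon[seq_len(n_tip)]; tip_lat <- lat[seq_len(n_tip)]

    coords <- cbind(tip_lon, tip_lat)
    n_distinct <- nrow(unique(coords))
    areas <- if (m_areas == 1 || n_distinct < m_areas) {
      # degenerate geography (e.g. zero diffusion): one area per location
      as.integer(factor(paste(tip_lon, tip_lat)))
    } else {
      kmeans(coords, centers = m_areas, nstart = 5)$cluster
    }

    ## families: tips below each edge crossing age `family_depth`
    cut_time <- H - family_depth
    fam <- integer(n_tip)
    if (cut_time <= 0) {
      fam[] <- 1L
    } else {
      anc <- integer(n_all)
      anc[tree_o$edge[, 2]] <- tree_o$edge[, 1]
      for (i in seq_len(n_tip)) {
        node <- i
        while (node != root && depths[anc[node]] > cut_time) node <- anc[node]
        fam[i] <- node
      }
      fam <- as.integer(factor(fam))
    }
    data.frame(
      taxon = tree$tip.label, longitude = tip_lon, latitude = tip_lat,
      macroarea = paste0("area", areas), family = paste0("fam", fam),
      stringsAsFactors = FALSE
    )
  })
}

#' Jitter branch lengths to emulate a posterior tree sample
#'
#' Multiplies every branch length by independent lognormal noise
#' (`sdlog = jitter_sd`), producing trees that agree in topology but vary
#' in divergence times, a cheap stand-in for posterior tree uncertainty.
#'
#' @param tree a `phylo`.
#' @param n_trees number of trees in the sample.
#' @param jitter_sd lognormal sdlog of the multiplicative noise
#'   (default 0.1).
#' @param seed integer seed.
#' @return a `tree_sample`.
#' @export
jitter_tree_sample <- function(tree, n_trees = 10, jitter_sd = 0.1, seed = 1) {
  trees <- with_seed(seed, {
    lapply(seq_len(n_trees), function(i) {
      tr <- tree
      tr$edge.length <- tr$edge.length *
        rlnorm(length(tr$edge.length), meanlog = -jitter_sd^2 / 2,
               sdlog = jitter_sd)
      tr
    })
  })
  tree_sample(trees, source_size = n_trees, seed = seed)
}

#' Simulate a trait pair from the latent logistic (GLMM) model
#'
#' The result-part trait `y` is Bernoulli(p_y) iid; the condition-part
#' trait `x` follows `logit P(x=1) = a + b y + u_p + u_s` with
#' `u_p ~ N(0, sigma_p^2 C_phylo)` and `u_s ~ N(0, sigma_s^2 C_spatial)`
#' (covariances standardized by their maximum diagonal). With `b = 0` and
#' positive sigmas this generates phylogenetically/spatially confounded
#' null data.
#'
#' @param tree a `phylo`.
#' @param meta metadata for the tips (for the spatial kernel).
#' @param b fixed effect (log odds) of `y` on `x`.
#' @param sigma_p,sigma_s random-effect SDs.
#' @param intercept intercept `a`.
#' @param p_y marginal probability of the result trait (default 0.5).
#' @param length_scale_km spatial kernel scale.
#' @param seed integer seed.
#' @param y_sigma_p optional phylogenetic SD for a latent-logit simulation
#'   of `y` itself (default 0: iid).
#' @return list with `x`, `y` (named integer vectors) and the latent
#'   fields.
#' @export
simulate_glmm_traits <- function(tree, meta, b = 0, sigma_p = 0, sigma_s = 0,
                                 intercept = 0, p_y = 0.5,
                                 length_scale_km = 1000, seed = 1,
                                 y_sigma_p = 0) {
  taxa <- tree$tip.label
  n <- length(taxa)
  Cp <- phylo_covariance(tree, taxa, standardize = TRUE)
  Lp <- safe_chol(Cp)
  meta_i <- meta[match(taxa, meta$taxon), ]
  with_seed(seed, {
    u_p <- if (sigma_p > 0) sigma_p * drop(Lp %*% rnorm(n)) else numeric(n)
    u_s <- if (sigma_s > 0) {
      Cs <- spatial_covariance(meta_i, length_scale_km)
      sigma_s * drop(safe_chol(Cs) %*% rnorm(n))
    } else numeric(n)
    y <- if (y_sigma_p > 0) {
      eta_y <- log(p_y / (1 - p_y)) + y_sigma_p * drop(Lp %*% rnorm(n))
      rbinom(n, 1, plogis(eta_y))
    } else {
      rbinom(n, 1, p_y)
    }
    eta <- intercept + b * y + u_p + u_s
    x <- rbinom(n, 1, plogis(eta))
    list(x = setNames(as.integer(x), taxa), y = setNames(as.integer(y), taxa),
         u_p = u_p, u_s = u_s)
  })
}

#' Scenario definition for the synthetic-data generator
#'
#' @param n_tips tips in the base tree (default 300).
#' @param birth_rate Yule rate (default 1).
#' @param tree_height rescale the tree to this height (default 1, so rates
#'   of order 1 produce a handful of changes per lineage).
#' @param diffusion Brownian coordinate variance per unit branch length.
#' @param m_areas macro-areas.
#' @param family_depth family age threshold (default a third of the
#'   height).
#' @param n_trees trees in the jittered sample.
#' @param jitter_sd lognormal branch jitter.
#' @param universals list of per-universal generating models; each entry is
#'   a list with `id`, `utype`, and `model` = one of
#'   `list(type = "ctmc_dependent", rates = <8 named>)`,
#'   `list(type = "ctmc_independent", rates = <4 named>)`,
#'   `list(type = "glmm", b =, sigma_p =, sigma_s =, intercept =)`.
#' @param missingness MCAR missing-entry probability in [0, 1).
#' @param seed master seed.
#' @return a `scenario` list.
#' @export
scenario <- function(n_tips = 300, birth_rate = 1, tree_height = 1,
                     diffusion = 200, m_areas = 4, family_depth = NULL,
                     n_trees = 10, jitter_sd = 0.1, universals = list(),
                     missingness = 0, seed = 1) {
  if (missingness < 0 || missingness >= 1) stop("missingness must be in [0, 1)")
  if (n_tips < 2) stop("n_tips must be >= 2")
  structure(as.list(environment()), class = "scenario")
}

#' Generate a full synthetic dataset from a scenario
#'
#' Produces everything the pipeline consumes: a jittered tree sample, a
#' binary trait matrix with two features per universal (named `<id>_X`,
#' `<id>_Y`), tip metadata, the universal specs, and a truth record with
#' every generating parameter.
#'
#' @param sc a `scenario`.
#' @return list with `trees`, `traits`, `meta`, `specs`, `truth`,
#'   `base_tree`.
#' @export
generate_scenario <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  tree <- simulate_tree(sc$n_tips, sc$birth_rate,
                        seed = split_seed(sc$seed, "scenario", "tree"),
                        height = sc$tree_height)
  meta <- simulate_metadata(tree, sc$diffusion, sc$m_areas, sc$family_depth,
                            seed = split_seed(sc$seed, "scenario", "meta"))
  trees <- jitter_tree_sample(tree, sc$n_trees, sc$jitter_sd,
                              seed = split_seed(sc$seed, "scenario", "jitter"))
  taxa <- tree$tip.label
  traits <- NULL
  specs <- list()
  truth <- list()
  for (u in sc$universals) {
    if (is.null(u$id) || is.null(u$model)) stop("universal entry needs id and model")
    mdl <- u$model
    seed_u <- split_seed(sc$seed, u$id, "traits")
    if (mdl$type %in% c("ctmc_dependent", "ctmc_independent")) {
      kind <- sub("ctmc_", "", mdl$type)
      Q <- build_q(rate_model(kind, mdl$rates))
      states <- simulate_evolution(tree, Q, root_state = mdl$root %||% rep(0.25, 4),
                                   seed = seed_u)
      xy <- decode_four_state(states)
      x <- setNames(xy[, "x"], taxa); y <- setNames(xy[, "y"], taxa)
    } else if (mdl$type == "glmm") {
      sim <- simulate_glmm_traits(tree, meta, b = mdl$b %||% 0,
                                  sigma_p = mdl$sigma_p %||% 0,
                                  sigma_s = mdl$sigma_s %||% 0,
                                  intercept = mdl$intercept %||% 0,
                                  p_y = mdl$p_y %||% 0.5,
                                  y_sigma_p = mdl$y_sigma_p %||% 0,
                                  seed = seed_u)
      x <- sim$x; y <- sim$y
    } else {
      stop(sprintf("unknown trait model type '%s'", mdl$type))
    }
    cols <- cbind(x, y)
    colnames(cols) <- paste0(u$id, c("_X", "_Y"))
    traits <- if (is.null(traits)) cols else cbind(traits, cols)
    specs[[u$id]] <- universal_spec(
      u$id, u$utype %||% "other",
      condition = list(list(feature = paste0(u$id, "_X"), value = 1)),
      result = list(feature = paste0(u$id, "_Y"), value = 1),
      description = sprintf("synthetic universal generated by %s", mdl$type)
    )
    truth[[u$id]] <- mdl
  }
  if (!is.null(traits) && sc$missingness > 0) {
    mask <- with_seed(split_seed(sc$seed, "scenario", "missing"), {
      matrix(runif(length(traits)) < sc$missingness, nrow(traits))
    })
    traits[mask] <- NA_integer_
  }
  list(trees = trees, traits = traits, meta = meta, specs = unname(specs),
       truth = truth, base_tree = tree)
}
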