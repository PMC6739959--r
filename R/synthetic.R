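# Synthetic-data generator emulating a two-lifestyle, two-structure
# comparative morphometric study: smooth landmark templates with
# semilandmark curves, a pure-birth phylogeny, species mean shapes evolved
# by Brownian motion with a controllable partial-warp spectrum exponent,
# lifestyle mean offset, group disparity ratio and cross-structure
# integration, and per-species specimen sampling with allometry, digitizing
# noise and replicate digitizations.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generator configuration
#'
#' Bundles every knob of the synthetic study generator. Defaults emulate the
#' design of a 37-species, two-lifestyle comparative study of two structures
#' (a 36-point humerus-like and a 38-point mandible-like template).
#'
#' @param nSpecies number of species (tree tips).
#' @param groupFraction subterranean share of species.
#' @param groupAssignment \code{"clade"} (lifestyle follows one clade, the
#'   realistic case) or \code{"random"}.
#' @param bmRate total Brownian shape variance accumulated over unit tree
#'   depth (Procrustes units squared), for the subterranean baseline.
#' @param groupMeanOffset magnitude (Procrustes distance) of the lifestyle
#'   effect on the mean shape; the offset direction is aligned across
#'   structures so lifestyle drives cross-structure covariation.
#' @param disparityRatio within-group variance ratio,
#'   non-subterranean / subterranean.
#' @param integrationRho latent cross-structure correlation in [0, 1]; a
#'   single value, or a named vector
#'   \code{c(subterranean = ., "non-subterranean" = .)} for group-specific
#'   integration.
#' @param factorShare share of the non-uniform shape variance carried by the
#'   shared latent direction (the channel through which
#'   \code{integrationRho} acts).
#' @param allometrySlope magnitude of the allometric shape displacement per
#'   relative centroid-size deviation.
#' @param allometryAngle angle in degrees between the two groups' allometric
#'   directions (0 = common slope).
#' @param csBase,csSdLog lognormal centroid-size distribution of specimens.
#' @param specimenNoiseSd isotropic per-coordinate within-species noise.
#' @param replicateNoiseSd isotropic per-coordinate digitization noise for
#'   the triplicate replicas (0 disables replicas).
#' @param spectrumExponent c: partial-warp variance proportional to
#'   lambda^(-c) (1 = self-similar).
#' @param uniformVarShare share of total shape variance in the affine
#'   (uniform) component, which carries no bending energy.
#' @param sampleSizes \code{"table1"} (skewed, range 2-59, emulating real
#'   museum samples) or \code{"balanced"}.
#' @param nPerSpecies specimens per species under \code{"balanced"}.
#' @param seed master seed; identical configurations give bit-identical
#'   output.
#' @return a validated list of class \code{GeneratorConfig}.
#' @export
generatorConfig <- function(nSpecies = 37, groupFraction = 0.5,
                            groupAssignment = c("clade", "random"),
                            bmRate = 0.02, groupMeanOffset = 0.1,
                            disparityRatio = 4, integrationRho = 0.85,
                            factorShare = 0.5, allometrySlope = 0.05,
                            allometryAngle = 0, csBase = 10, csSdLog = 0.25,
                            specimenNoiseSd = 0.005, replicateNoiseSd = 0,
                            spectrumExponent = 1, uniformVarShare = 0.05,
                            sampleSizes = c("table1", "balanced"),
                            nPerSpecies = 5, seed = 1) {
  groupAssignment <- match.arg(groupAssignment)
  sampleSizes <- match.arg(sampleSizes)
  stopifnot(nSpecies >= 3, groupFraction > 0, groupFraction < 1,
            bmRate > 0, disparityRatio > 0,
            all(integrationRho >= 0), all(integrationRho <= 1),
            factorShare >= 0, factorShare <= 1,
            specimenNoiseSd >= 0, replicateNoiseSd >= 0,
            spectrumExponent >= 0, uniformVarShare >= 0, uniformVarShare < 1)
  if (length(integrationRho) == 1L)
    integrationRho <- c(subterranean = unname(integrationRho),
                        "non-subterranean" = unname(integrationRho))
  if (!setequal(names(integrationRho), c("subterranean", "non-subterranean")))
    stop("integrationRho must be one value or named per group")
  structure(list(
    nSpecies = nSpecies, groupFraction = groupFraction,
    groupAssignment = groupAssignment, bmRate = bmRate,
    groupMeanOffset = groupMeanOffset, disparityRatio = disparityRatio,
    integrationRho = integrationRho, factorShare = factorShare,
    allometrySlope = allometrySlope, allometryAngle = allometryAngle,
    csBase = csBase, csSdLog = csSdLog, specimenNoiseSd = specimenNoiseSd,
    replicateNoiseSd = replicateNoiseSd,
    spectrumExponent = spectrumExponent, uniformVarShare = uniformVarShare,
    sampleSizes = sampleSizes, nPerSpecies = nPerSpecies, seed = seed),
    class = "GeneratorConfig")
}

#' Landmark templates with semilandmark curves
#'
#' Deterministic smooth, non-self-intersecting outlines at unit centroid
#' size. \code{"humerus36"} has 36 points (22 fixed landmarks, 14
#' semilandmarks on four curve segments); \code{"mandible38"} has 38 points
#' (12 fixed landmarks, 26 semilandmarks on the outline between them). Every
#' slider's \code{before}/\code{after} neighbours are the adjacent outline
#' points. \code{"custom"} places \code{k} points on a smooth closed curve
#' with no sliders.
#'
#' @param kind template kind.
#' @param k landmark count for \code{"custom"}.
#' @return list with \code{template} (\code{k x 2}, unit centroid size),
#'   \code{sliders} (data.frame \code{before, slider, after}, 1-based) and
#'   \code{fixed} (indices of fixed landmarks).
#' @export
makeTemplate <- function(kind = c("humerus36", "mandible38", "custom"),
                         k = 20) {
  kind <- match.arg(kind)
  outline <- function(k, fr) {
    th <- 2 * pi * (seq_len(k) - 1) / k
    r <- fr(th)
    cbind(r * cos(th), r * sin(th))
  }
  if (kind == "humerus36") {
    k <- 36L
    pts <- outline(k, function(th)
      1 + 0.18 * cos(2 * th) + 0.10 * sin(3 * th) + 0.05 * cos(5 * th))
    sl <- c(12:14, 16:18, 29:32, 33:36)
  } else if (kind == "mandible38") {
    k <- 38L
    pts <- outline(k, function(th)
      1 + 0.12 * cos(2 * th) + 0.08 * sin(3 * th) + 0.04 * sin(5 * th))
    pts[, 1] <- pts[, 1] * 1.8   # elongated ramus
    fixed <- c(1, 2, 3, 4, 5, 9, 13, 17, 18, 24, 30, 38)
    sl <- setdiff(seq_len(k), fixed)
  } else {
    pts <- outline(k, function(th) 1 + 0.1 * cos(2 * th))
    sl <- integer(0)
  }
  pts <- .center(pts)
  pts <- pts / sqrt(sum(pts^2))
  sliders <- if (length(sl))
    data.frame(before = ifelse(sl - 1 < 1, k, sl - 1), slider = sl,
               after = ifelse(sl + 1 > k, 1, sl + 1))
  else data.frame(before = integer(0), slider = integer(0),
                  after = integer(0))
  list(template = pts, sliders = sliders,
       fixed = setdiff(seq_len(nrow(pts)), sl))
}

#' Simulate a pure-birth phylogeny
#'
#' Pure-birth (Yule) tree rescaled to unit depth, tips labelled
#' \code{sp001...}; deterministic per seed.
#'
#' @param nTips number of tips (>= 3).
#' @param seed integer seed.
#' @return an ape \code{phylo}.
#' @export
simulateTree <- function(nTips, seed = 1) {
  stopifnot(nTips >= 3)
  tr <- .withSeed(seed, ape::rphylo(nTips, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%03d", seq_len(nTips))
  tr
}

# Lifestyle assignment: one clade of about groupFraction * N tips, or random.
.assignGroups <- function(tree, config) {
  N <- length(tree$tip.label)
  target <- round(config$groupFraction * N)
  if (config$groupAssignment == "clade") {
    parts <- ape::prop.part(tree)
    sizes <- lengths(parts)
    best <- which.min(abs(sizes - target))
    sub <- tree$tip.label[parts[[best]]]
  } else {
    sub <- .withSeed(config$seed + 7L,
                     sample(tree$tip.label, target))
  }
  g <- ifelse(tree$tip.label %in% sub, "subterranean", "non-subterranean")
  names(g) <- tree$tip.label
  g
}

# One Brownian-motion sample per column: N x m matrix with tip covariance C.
.bmSample <- function(Lchol, m) Lchol %*% matrix(stats::rnorm(nrow(Lchol) * m),
                                                 nrow(Lchol), m)

#' Simulate species mean shapes for both structures
#'
#' Shape deviations evolve by Brownian motion on the tree in the
#' partial-warp basis of each template, with per-warp variance proportional
#' to lambda^(-c) so the global-integration slope is an analytic target, plus
#' a small uniform (affine) component. A shared Brownian latent factor,
#' entering each structure along a fixed spectrum-shaped direction with
#' group-specific loading sqrt(rho), induces cross-structure covariation of
#' strength rho. Subterranean species receive a fixed mean offset along a
#' deformation direction aligned across structures, and non-subterranean
#' deviations are scaled to realize the configured disparity ratio.
#'
#' @param config a [generatorConfig()].
#' @param tree a phylogeny over \code{config$nSpecies} tips (defaults to
#'   [simulateTree()] under the config seed).
#' @return list with per-structure elements \code{humerus} and
#'   \code{mandible} (each holding \code{means}: \code{k x 2 x N} array,
#'   \code{template}, \code{sliders}, \code{spectrum}, \code{latent}: the
#'   species scores on the shared factor), the \code{species} table
#'   (species, group) and the \code{tree}.
#' @export
simulateSpeciesShapes <- function(config, tree = NULL) {
  if (is.null(tree)) tree <- simulateTree(config$nSpecies, config$seed)
  if (length(tree$tip.label) != config$nSpecies)
    stop("tree tip count does not match config$nSpecies")
  groups <- .assignGroups(tree, config)
  C <- bmCovariance(tree)
  Lchol <- t(chol(C + 1e-12 * diag(nrow(C))))
  N <- nrow(C)
  # expected within-group variance per unit Brownian rate depends on each
  # group's clade covariance; scale the non-subterranean rate so the
  # EXPECTED within-group variance ratio equals disparityRatio
  vGroup <- vapply(c("subterranean", "non-subterranean"), function(g) {
    Cg <- C[groups == g, groups == g, drop = FALSE]
    ng <- nrow(Cg)
    sum(diag(Cg)) / ng - sum(Cg) / ng^2
  }, numeric(1))
  rateScale <- ifelse(groups == "non-subterranean",
                      sqrt(config$disparityRatio * vGroup[1] / vGroup[2]), 1)

  .withSeed(config$seed + 101L, {
    v0 <- as.numeric(.bmSample(Lchol, 1))   # shared latent factor
    out <- list()
    for (s in c("humerus", "mandible")) {
      tpl <- makeTemplate(if (s == "humerus") "humerus36" else "mandible38")
      spec <- bendingSpectrum(tpl$template)
      m <- length(spec@values)
      V <- spec@vectors
      cexp <- config$spectrumExponent
      sj <- spec@values^(-cexp / 2)
      Vnu <- config$bmRate * (1 - config$uniformVarShare)
      f <- config$factorShare
      a <- sqrt((1 - f) * Vnu / (2 * sum(sj^2)))
      q <- c(sj, sj) / sqrt(2 * sum(sj^2))   # shared-direction pattern
      b <- sqrt(f * Vnu)

      rho <- config$integrationRho[groups]
      w <- as.numeric(.bmSample(Lchol, 1))   # structure-specific latent
      vS <- sqrt(rho) * v0 + sqrt(1 - rho) * w

      Z <- .bmSample(Lchol, 2 * m)           # independent warp deviations
      scores <- sweep(Z, 2, a * c(sj, sj), "*") + b * outer(vS, q)
      scores <- scores * rateScale           # group disparity scaling
      # calibrate the REALIZED within-group variance ratio to disparityRatio
      # exactly: a single Brownian draw scatters widely around its
      # expectation, so the non-subterranean deviations (about their group
      # mean) are rescaled to hit the configured ratio in this realization
      vReal <- vapply(c("subterranean", "non-subterranean"), function(g) {
        Sg <- scores[groups == g, , drop = FALSE]
        sum(sweep(Sg, 2, colMeans(Sg))^2) / nrow(Sg)
      }, numeric(1))
      idx <- groups == "non-subterranean"
      gm <- colMeans(scores[idx, , drop = FALSE])
      adj <- sqrt(config$disparityRatio * vReal[1] / vReal[2])
      scores[idx, ] <- sweep(scores[idx, , drop = FALSE], 2, gm) * adj +
        rep(gm, each = sum(idx))

      # uniform (affine) component, Brownian as well
      tau <- sqrt(config$uniformVarShare * config$bmRate / 2)
      Bu <- .bmSample(Lchol, 4) * tau

      # lifestyle offset: fixed mid-scale deformation, aligned across
      # structures through the shared sign pattern
      o <- numeric(2 * m)
      o[c(2, 3, m + 2, m + 3)] <- c(1, -1, 1, -1)
      o <- o / sqrt(sum(o^2))
      off <- ifelse(groups == "subterranean", config$groupMeanOffset, 0)
      scores <- scores + outer(off, o)

      means <- array(0, dim = c(nrow(tpl$template), 2L, N),
                     dimnames = list(NULL, c("x", "y"), tree$tip.label))
      for (i in seq_len(N)) {
        devx <- V %*% scores[i, seq_len(m)]
        devy <- V %*% scores[i, m + seq_len(m)]
        A <- matrix(Bu[i, ], 2, 2) * rateScale[i]
        means[, , i] <- tpl$template + cbind(devx, devy) +
          tpl$template %*% t(A)
      }
      out[[s]] <- list(means = means, template = tpl$template,
                       sliders = tpl$sliders, spectrum = spec,
                       latent = vS, warpScores = scores)
    }
    out$species <- data.frame(species = tree$tip.label,
                              group = unname(groups))
    out$tree <- tree
    out
  })
}

#' Simulate specimens (and optional digitization replicates) per species
#'
#' Each specimen is its species mean plus an allometric displacement driven
#' by a lognormally drawn centroid size (slope direction per group, rotated
#' by \code{allometryAngle} for the non-subterranean group) and isotropic
#' landmark noise. When \code{replicateNoiseSd > 0}, three replicate
#' digitizations of every specimen are produced.
#'
#' @param means \code{k x 2 x N} species mean array (one structure), species
#'   names in \code{dimnames[[3]]}.
#' @param config a [generatorConfig()].
#' @param species the species/group table from [simulateSpeciesShapes()].
#' @param structure label written into the specimen table.
#' @param seedOffset increment added to the config seed (so the two
#'   structures draw independent noise).
#' @return list with \code{landmarks} (\linkS4class{LandmarkSet}),
#'   \code{table} (specimen_id, species, group, structure, cs) and
#'   \code{replicates} (list of 3 LandmarkSets, or NULL).
#' @export
simulateSpecimens <- function(means, config, species,
                              structure = "humerus", seedOffset = 0L) {
  N <- dim(means)[3]
  k <- dim(means)[1]
  spNames <- dimnames(means)[[3]]
  grp <- species$group[match(spNames, species$species)]
  .withSeed(config$seed + 1000L + seedOffset, {
    ni <- if (config$sampleSizes == "balanced")
      rep(config$nPerSpecies, N)
    else pmin(pmax(stats::rnbinom(N, mu = 8, size = 1.2) + 2L, 2L), 59L)
    # group allometric directions: unit coordinate-space vectors in a fixed
    # 2-plane, separated by allometryAngle degrees
    base1 <- sin(2 * pi * seq_len(2 * k) / (2 * k))
    base2 <- cos(2 * pi * seq_len(2 * k) / (2 * k))
    base1 <- base1 / sqrt(sum(base1^2))
    base2 <- base2 - sum(base2 * base1) * base1
    base2 <- base2 / sqrt(sum(base2^2))
    ang <- config$allometryAngle * pi / 180
    dirs <- list(subterranean = base1,
                 "non-subterranean" = cos(ang) * base1 + sin(ang) * base2)
    total <- sum(ni)
    a <- array(0, dim = c(k, 2L, total))
    ids <- character(total)
    tab <- vector("list", N)
    pos <- 0L
    for (i in seq_len(N)) {
      cs <- stats::rlnorm(ni[i], meanlog = log(config$csBase),
                          sdlog = config$csSdLog)
      for (j in seq_len(ni[i])) {
        pos <- pos + 1L
        dev <- config$allometrySlope *
          ((cs[j] - config$csBase) / config$csBase) * dirs[[grp[i]]]
        # disparity ratio also governs the within-species noise channel
        nsd <- config$specimenNoiseSd *
          if (grp[i] == "non-subterranean") sqrt(config$disparityRatio) else 1
        shp <- means[, , i] + cbind(dev[seq_len(k)], dev[k + seq_len(k)]) +
          matrix(stats::rnorm(2 * k, sd = nsd), k, 2)
        a[, , pos] <- shp * cs[j]   # specimens carry size
        ids[pos] <- sprintf("%s_s%02d", spNames[i], j)
      }
      tab[[i]] <- data.frame(specimen_id = ids[(pos - ni[i] + 1L):pos],
                             species = spNames[i], group = grp[i],
                             structure = structure,
                             cs = cs)
    }
    dimnames(a) <- list(NULL, c("x", "y"), ids)
    reps <- NULL
    if (config$replicateNoiseSd > 0) {
      reps <- lapply(1:3, function(r) {
        b <- a + array(stats::rnorm(length(a),
                                    sd = config$replicateNoiseSd *
                                         config$csBase),
                       dim = dim(a))
        dimnames(b) <- dimnames(a)
        landmarkSet(b)
      })
    }
    list(landmarks = landmarkSet(a), table = do.call(rbind, tab),
         replicates = reps)
  })
}

#' Simulate a partial-warp-spectrum sample
#'
#' Draws n shapes around a reference with independent per-warp scores whose
#' variance is proportional to lambda^(-c): the analytic anchor for the
#' global-integration regression (slope -c).
#'
#' @param n number of shapes.
#' @param exponent spectrum exponent c (>= 0).
#' @param template template kind passed to [makeTemplate()].
#' @param totalVar total non-affine shape variance.
#' @param seed integer seed.
#' @return list with \code{shapes} (\code{k x 2 x n} array) and
#'   \code{spectrum}.
#' @export
simulateWarpSample <- function(n, exponent = 1, template = "humerus36",
                               totalVar = 0.01, seed = 1) {
  tpl <- makeTemplate(template)
  spec <- bendingSpectrum(tpl$template)
  m <- length(spec@values)
  sj <- spec@values^(-exponent / 2)
  sj <- sj * sqrt(totalVar / (2 * sum(sj^2)))
  .withSeed(seed, {
    a <- array(0, dim = c(nrow(tpl$template), 2L, n))
    for (i in seq_len(n)) {
      sx <- stats::rnorm(m, sd = sj)
      sy <- stats::rnorm(m, sd = sj)
      a[, , i] <- tpl$template + cbind(spec@vectors %*% sx,
                                       spec@vectors %*% sy)
    }
    list(shapes = a, spectrum = spec)
  })
}

#' Simulate two variable blocks sharing one latent factor
#'
#' Independent-specimen convenience generator for integration analyses: both
#' blocks load a common standard-normal factor so their population
#' first-pair PLS correlation equals \code{rho}.
#'
#' @param n specimens.
#' @param p1,p2 block widths.
#' @param rho latent cross-block correlation in [0, 1].
#' @param factorSd standard deviation of the factor's loading column
#'   relative to unit residual noise.
#' @param seed integer seed.
#' @return list with matrices \code{Y1}, \code{Y2}.
#' @export
simulateCorrelatedBlocks <- function(n, p1 = 8, p2 = 8, rho = 0.9,
                                     factorSd = 3, seed = 1) {
  stopifnot(rho >= 0, rho <= 1)
  .withSeed(seed, {
    f <- stats::rnorm(n)
    mk <- function(p) {
      v <- if (rho == 1) f else
        sqrt(rho) * f + sqrt(1 - rho) * stats::rnorm(n)
      cbind(factorSd * v, matrix(stats::rnorm(n * (p - 1)), n, p - 1))
    }
    list(Y1 = mk(p1), Y2 = mk(p2))
  })
}

#' Write a synthetic study to disk
#'
#' Emits the full file set an external pipeline would read: per-structure TPS
#' and slider CSV, a specimen table CSV, the Newick tree, and a provenance
#' JSON echoing the configuration.
#'
#' @param config a [generatorConfig()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
writeStudy <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulateSpeciesShapes(config)
  paths <- character(0)
  tabs <- list()
  for (s in c("humerus", "mandible")) {
    sp <- simulateSpecimens(sim[[s]]$means, config, sim$species,
                            structure = s,
                            seedOffset = if (s == "humerus") 0L else 1L)
    p <- file.path(dir, paste0(s, ".tps"))
    writeTPS(sp$landmarks, p)
    ps <- file.path(dir, paste0(s, "_sliders.csv"))
    writeSliderTable(sim[[s]]$sliders, ps)
    paths <- c(paths, p, ps)
    tabs[[s]] <- sp$table
  }
  pt <- file.path(dir, "specimens.csv")
  utils::write.csv(do.call(rbind, tabs), pt, row.names = FALSE)
  pn <- file.path(dir, "tree.nwk")
  ape::write.tree(sim$tree, pn)
  pj <- file.path(dir, "provenance.json")
  jsonlite::write_json(unclass(config), pj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, pt, pn, pj))
}
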