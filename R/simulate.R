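# Forward-time simulation of phylogenies under the nine diversification
# scenarios, pruning to reconstructed trees, random tip subsampling, and
# the batch classification-experiment harness.
#
# Waiting times between events use the total event rate evaluated at the
# time of the previous event (not exact thinning of the inhomogeneous
# process); for constant-rate models this is exact, and for slowly varying
# rates the discrepancy is negligible (see the methods vignette).

# ---- internal: build an ape phylo from merge records ----------------------

# merges: list of integer child vectors (raw ids: tips 1..ntips, internal
# raw id ntips + j for merge j); depths: time before present of each merge
.build_phylo <- function(merges, depths, ntips, tip_labels = NULL) {
  nint <- length(merges)
  ord <- order(depths, decreasing = TRUE)           # root first
  final_id <- integer(nint)
  final_id[ord] <- ntips + seq_len(nint)
  map <- function(raw) {
    out <- raw
    int <- raw > ntips
    out[int] <- final_id[raw[int] - ntips]
    out
  }
  parent <- integer(0); child <- integer(0); plen <- numeric(0)
  node_depth <- c(rep(0, ntips), depths)
  for (jj in seq_len(nint)) {
    kids <- merges[[jj]]
    parent <- c(parent, rep(final_id[jj], length(kids)))
    child <- c(child, map(kids))
    plen <- c(plen, depths[jj] - node_depth[kids])
  }
  tr <- structure(list(
    edge = cbind(parent, child, deparse.level = 0),
    edge.length = plen,
    tip.label = tip_labels %||% paste0("t", seq_len(ntips)),
    Nnode = nint
  ), class = "phylo", order = NULL)
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate a saturated-diversity (Moran-type turnover) phylogeny
#'
#' Forward-time simulation of the constant-diversity scenarios M1 and M2:
#' the clade holds exactly `N0` species at all times, and turnover events
#' (an extinction immediately followed by a speciation) occur at total
#' rate `N0 * tau(t)`.  At each event one uniformly chosen lineage is
#' removed and another uniformly chosen lineage bifurcates.  The process
#' starts from `N0` lineages joined by an artificial root polytomy and
#' runs until `duration`; the returned reconstructed tree is the
#' genealogy of the `N0` extant species.  Waiting times are drawn from an
#' exponential with the rate evaluated at the previous event (exact when
#' `gamma = 0`).
#'
#' If the initial polytomy has not fully resolved by `duration` (i.e. the
#' extant species do not share a common ancestor within the simulated
#' window), the simulation is re-run with the duration doubled, up to
#' `max_extensions` times; if it still persists the tree is returned with
#' a root polytomy and flagged.
#'
#' @param N0 Clade size (>= 2), constant through time.
#' @param tau0 Turnover rate at present (> 0).
#' @param gamma Exponential variation coefficient of the turnover rate
#'   (`tau(t) = tau0 * exp(gamma * t)`, t backwards from the present);
#'   0 gives model M1.
#' @param duration Simulated time span; default `10 * N0 / tau0`, about
#'   ten times the expected time to the most recent common ancestor.
#' @param seed Optional integer seed.
#' @param max_extensions Number of automatic duration doublings allowed.
#' @return An object of class `"sim_tree"`: the reconstructed `phylo`
#'   (`$tree`), the generating model and parameters, the realized extant
#'   count (`$extant`, always `N0` here) and a `root_polytomy` flag.
#' @export
simulate_saturated <- function(N0, tau0, gamma = 0, duration = NULL,
                               seed = NULL, max_extensions = 3) {
  if (N0 < 2) stop("N0 must be >= 2")
  if (tau0 <= 0) stop("tau0 must be > 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(duration)) duration <- 10 * N0 / tau0
  if (duration <= 0) stop("duration must be > 0")

  attempt <- 0
  repeat {
    res <- .sim_saturated_once(N0, tau0, gamma, duration)
    if (!res$root_polytomy || attempt >= max_extensions) break
    attempt <- attempt + 1
    duration <- duration * 2
  }
  structure(list(
    tree = res$tree, model = if (gamma == 0) "M1" else "M2",
    params = c(tau0 = tau0, gamma = gamma), N0 = N0, extant = N0,
    duration = duration, root_polytomy = res$root_polytomy,
    extensions = attempt
  ), class = "sim_tree")
}

.sim_saturated_once <- function(N0, tau0, gamma, duration) {
  # forward event times; tau at forward time s is tau0 * exp(gamma*(D - s))
  if (gamma == 0) {
    times <- numeric(0); t_last <- 0
    repeat {                       # draw in chunks until duration exceeded
      k <- max(256L, ceiling(1.2 * N0 * tau0 * (duration - t_last)))
      new <- t_last + cumsum(stats::rexp(k, rate = N0 * tau0))
      times <- c(times, new)
      t_last <- times[length(times)]
      if (t_last > duration) break
    }
    times <- times[times <= duration]
  } else {
    times <- numeric(0); s <- 0
    repeat {
      rate <- N0 * tau0 * exp(gamma * (duration - s))
      s <- s + stats::rexp(1, rate)
      if (s > duration) break
      times <- c(times, s)
    }
  }
  K <- length(times)
  victim <- sample.int(N0, K, replace = TRUE)
  other <- sample.int(N0 - 1L, K, replace = TRUE)
  parent <- other + (other >= victim)       # uniform among the N0 - 1 others

  # backwards ancestry reconstruction over the event record
  act <- seq_len(N0)                        # slot -> active node id (0 = none)
  n_active <- N0
  mc1 <- integer(N0 - 1); mc2 <- integer(N0 - 1); md <- numeric(N0 - 1)
  nm <- 0L
  if (K > 0) for (i in K:1) {
    v <- victim[i]; p <- parent[i]
    av <- act[v]; ap <- act[p]
    if (av > 0L) {
      if (ap > 0L) {                        # coalescence of av and ap
        nm <- nm + 1L
        mc1[nm] <- av; mc2[nm] <- ap; md[nm] <- duration - times[i]
        act[p] <- N0 + nm
        n_active <- n_active - 1L
      } else {
        act[p] <- av
      }
      act[v] <- 0L
    }
    if (n_active == 1L) break
  }
  root_polytomy <- n_active > 1L
  merges <- c(
    lapply(seq_len(nm), function(j) c(mc1[j], mc2[j])),
    if (root_polytomy) list(act[act > 0L])
  )
  depths <- c(md[seq_len(nm)], if (root_polytomy) duration)
  list(tree = .build_phylo(merges, depths, N0), root_polytomy = root_polytomy)
}

#' Simulate an expanding-diversity (birth-death) phylogeny
#'
#' Forward-time simulation of the birth-death scenarios M3-M6, starting
#' from a single lineage.  Events occur at total rate
#' `N_current * (lambda + mu)` with the rates evaluated at the previous
#' event time; at each event a uniformly chosen lineage either bifurcates
#' (probability `lambda/(lambda+mu)`) or dies.  The process runs until
#' `duration` is exceeded or the clade dies out.  The reconstructed tree
#' prunes all lineages without extant descendants; its tips all sit at
#' the stop time, so it is exactly ultrametric.
#'
#' Replicates in which fewer than `min_extant` species survive are
#' discarded and re-simulated (conditioning on survival to the present),
#' up to `max_tries` times; the number of discards is recorded.
#'
#' @param spec A [diversification_model()] object with model M3, M4a,
#'   M4b, M4c, M4d, M5 or M6.  Rates are anchored at the present, i.e. at
#'   `t = 0` backwards equals forward time `duration`; the `N0` stored in
#'   the model object plays no role in the simulation (the realized
#'   extant count does).
#' @param duration Simulated time span (> 0).
#' @param seed Optional integer seed.
#' @param min_extant Minimum number of surviving species required (>= 2).
#' @param max_tries Attempts before giving up with an error.
#' @param max_lineages Safety cap on standing diversity.
#' @return A `"sim_tree"` object; `$extant` is the realized number of
#'   extant species and `$discards` the number of rejected replicates.
#' @export
simulate_birth_death <- function(spec, duration, seed = NULL,
                                 min_extant = 3, max_tries = 1000,
                                 max_lineages = 1e5) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$model %in% c("M3", "M4a", "M4b", "M4c", "M4d", "M5", "M6"))
    stop("birth-death simulation applies to models M3-M6; use ",
         "simulate_saturated() for M1/M2")
  if (duration <= 0) stop("duration must be > 0")
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_tries)) {
    res <- .sim_bd_once(spec, duration, max_lineages)
    if (res$extant >= min_extant) {
      return(structure(list(
        tree = res$tree, model = spec$model, params = spec$params,
        N0 = res$extant, extant = res$extant, duration = duration,
        root_polytomy = FALSE, discards = try - 1L
      ), class = "sim_tree"))
    }
  }
  stop("clade failed to survive with >= ", min_extant, " species in ",
       max_tries, " attempts; increase duration or rates")
}

.sim_bd_once <- function(spec, duration, max_lineages) {
  cap <- 1024L
  l_parent <- integer(cap); l_start <- numeric(cap)
  l_end <- rep(NA_real_, cap); l_split <- logical(cap)
  nl <- 1L; l_parent[1] <- 0L; l_start[1] <- 0
  alive <- 1L
  s <- 0
  repeat {
    na <- length(alive)
    if (na == 0L) break
    if (na > max_lineages)
      stop("standing diversity exceeded max_lineages = ", max_lineages)
    r <- rates_at(spec, duration - s)
    lam <- r$speciation; mu <- r$extinction
    tot <- na * (lam + mu)
    if (tot <= 0) break
    s <- s + stats::rexp(1, tot)
    if (s > duration) break
    i <- alive[sample.int(na, 1)]
    if (nl + 2L > cap) {                     # grow storage
      cap <- cap * 2L
      length(l_parent) <- cap; length(l_start) <- cap
      l_end <- c(l_end, rep(NA_real_, cap - length(l_end)))
      length(l_split) <- cap
    }
    if (stats::runif(1) < lam / (lam + mu)) {          # speciation
      l_end[i] <- s; l_split[i] <- TRUE
      c1 <- nl + 1L; c2 <- nl + 2L; nl <- nl + 2L
      l_parent[c1] <- i; l_parent[c2] <- i
      l_start[c1] <- s; l_start[c2] <- s
      alive <- c(alive[alive != i], c1, c2)
    } else {                                            # extinction
      l_end[i] <- s; l_split[i] <- FALSE
      alive <- alive[alive != i]
    }
  }
  extant <- alive
  if (length(extant) < 2)
    return(list(tree = NULL, extant = length(extant)))
  l_parent <- l_parent[seq_len(nl)]
  l_end <- l_end[seq_len(nl)]

  # prune to lineages with extant descendants
  has <- logical(nl)
  has[extant] <- TRUE
  for (i in nl:1) if (has[i] && l_parent[i] > 0L)
    has[l_parent[i]] <- TRUE
  kids <- vector("list", nl)
  for (i in seq_len(nl)) {
    p <- l_parent[i]
    if (p > 0L && has[i]) kids[[p]] <- c(kids[[p]], i)
  }
  is_tip <- seq_len(nl) %in% extant
  tip_id <- integer(nl); tip_id[extant] <- seq_along(extant)

  merges <- list(); depths <- numeric(0)
  # returns the raw node id (tip id or ntips + merge index) subtending
  # lineage i in the reconstructed tree
  ntips <- length(extant)
  descend <- function(i) {
    repeat {
      if (is_tip[i]) return(tip_id[i])
      ch <- kids[[i]]
      if (length(ch) == 2L) {
        a <- descend(ch[1]); b <- descend(ch[2])
        merges[[length(merges) + 1L]] <<- c(a, b)
        depths[length(depths) + 1L] <<- duration - l_end[i]
        return(ntips + length(merges))
      }
      i <- ch[1]                              # chain through pruned split
    }
  }
  root_raw <- which(has & l_parent == 0L)
  descend(root_raw)
  list(tree = .build_phylo(merges, depths, ntips), extant = ntips)
}

#' @export
print.sim_tree <- function(x, ...) {
  cat("Simulated phylogeny under ", x$model, " (",
      paste(sprintf("%s = %g", names(x$params), x$params), collapse = ", "),
      ")\n", sep = "")
  cat("  extant species:", x$extant, " duration:", format(x$duration), "\n")
  if (isTRUE(x$root_polytomy)) cat("  NOTE: root polytomy unresolved\n")
  invisible(x)
}

#' Randomly subsample the tips of a phylogeny
#'
#' Retains `ceiling(f * n)` tips drawn uniformly without replacement and
#' prunes the rest, mimicking incomplete taxon sampling; unsampled
#' internal nodes of degree two are suppressed with branch lengths
#' summed, which lengthens terminal branches.
#'
#' @param tree A `phylo` or `"sim_tree"` object.
#' @param f Sampling fraction in (0, 1]; the subsample must keep at least
#'   3 tips.
#' @param seed Optional integer seed.
#' @return A `phylo` object with `ceiling(f * n)` tips.
#' @export
sample_tips <- function(tree, f, seed = NULL) {
  if (inherits(tree, "sim_tree")) tree <- tree$tree
  stopifnot(inherits(tree, "phylo"))
  if (f <= 0 || f > 1) stop("f must be in (0, 1]")
  n <- ape::Ntip(tree)
  m <- ceiling(f * n)
  if (m < 3) stop("subsample would keep ", m, " tips; need >= 3")
  if (m == n) return(tree)
  if (!is.null(seed)) set.seed(seed)
  keep <- sample(tree$tip.label, m)
  ape::keep.tip(tree, keep)
}

#' Batch model-classification experiment
#'
#' Simulates `n_reps` phylogenies under a generating model, randomly
#' subsamples a fraction `f` of the tips of each, fits the candidate
#' models by maximum likelihood, and tabulates which model wins by AICc
#' together with the winners of the three hypothesis partitions
#' (saturated vs expanding diversity, constant vs varying rates,
#' extinction vs none).
#'
#' @param generator A [diversification_model()] object describing the
#'   generating process.  For M1/M2 its `N0` is the (constant) clade
#'   size; for M3-M6 the realized extant count of each replicate is used
#'   as the known clade size when fitting.
#' @param n_reps Number of replicates (0 gives an empty result).
#' @param f Sampling fraction applied to each simulated tree.
#' @param duration Simulation time span; defaults to the saturated
#'   simulator's default for M1/M2, required for M3-M6.
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @param models Candidate model ids to fit (default all nine).
#' @param restarts Optimizer restarts per model fit.
#' @param kappa Coalescence-rate convention constant.
#' @return An object of class `"classification_experiment"` with elements
#'   `results` (one row per replicate: tip count, best model, hypothesis
#'   probabilities, extinction fraction, error message if any), `counts`
#'   (best-model tally) and `partition_counts` (winners per partition).
#'   Failed replicates are recorded, not fatal.
#' @export
run_classification_experiment <- function(generator, n_reps, f = 1,
                                          duration = NULL, seed = NULL,
                                          models = .MODEL_IDS,
                                          restarts = 10, kappa = 2) {
  stopifnot(inherits(generator, "model_spec"))
  base_seed <- if (is.null(seed)) sample.int(1e6, 1) else as.integer(seed)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rows[[r]] <- tryCatch({
      st <- if (generator$model %in% c("M1", "M2")) {
        simulate_saturated(
          N0 = generator$N0, tau0 = generator$params[["tau0"]],
          gamma = if (generator$model == "M2")
                    generator$params[["gamma"]] else 0,
          duration = duration, seed = base_seed + r)
      } else {
        if (is.null(duration))
          stop("duration is required for birth-death generators")
        simulate_birth_death(generator, duration = duration,
                             seed = base_seed + r)
      }
      tr <- if (f < 1) sample_tips(st, f) else st$tree
      cmp <- compare_models(coalescent_times(tr), N0 = st$extant,
                            models = models, restarts = restarts,
                            kappa = kappa)
      data.frame(rep = r, n = ape::Ntip(tr), best = cmp$best,
                 p_expanding = cmp$hypotheses$diversity[["expanding"]],
                 p_varying = cmp$hypotheses$rates[["varying"]],
                 p_extinction = cmp$hypotheses$extinction[["extinction"]],
                 extinction_fraction = cmp$extinction_fraction,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(rep = r, n = NA_integer_, best = NA_character_,
                 p_expanding = NA_real_, p_varying = NA_real_,
                 p_extinction = NA_real_, extinction_fraction = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  }
  results <- if (n_reps > 0) do.call(rbind, rows) else
    data.frame(rep = integer(0), n = integer(0), best = character(0),
               p_expanding = numeric(0), p_varying = numeric(0),
               p_extinction = numeric(0), extinction_fraction = numeric(0),
               error = character(0), stringsAsFactors = FALSE)
  ok <- !is.na(results$best)
  counts <- table(factor(results$best[ok], levels = models))
  partition_counts <- list(
    saturated  = sum(results$best[ok] %in% .PARTITIONS$diversity$B),
    expanding  = sum(results$best[ok] %in% .PARTITIONS$diversity$A),
    constant   = sum(results$best[ok] %in% .PARTITIONS$rates$B),
    varying    = sum(results$best[ok] %in% .PARTITIONS$rates$A),
    extinction = sum(results$best[ok] %in% .PARTITIONS$extinction$A),
    none       = sum(results$best[ok] %in% .PARTITIONS$extinction$B)
  )
  structure(list(generator = generator, f = f, n_reps = n_reps,
                 results = results, counts = counts,
                 partition_counts = partition_counts,
                 n_failed = sum(!ok)),
            class = "classification_experiment")
}

#' @export
print.classification_experiment <- function(x, ...) {
  cat("Model-classification experiment: generator ", x$generator$model,
      ", ", x$n_reps, " replicates, sampling fraction f = ", x$f, "\n\n",
      sep = "")
  if (x$n_reps == 0) { cat("  (no replicates)\n"); return(invisible(x)) }
  cat("Best-model counts:\n")
  print(x$counts)
  pc <- x$partition_counts
  cat(sprintf("\nPartition winners: saturated %d / expanding %d; constant %d / varying %d; extinction %d / none %d\n",
              pc$saturated, pc$expanding, pc$constant, pc$varying,
              pc$extinction, pc$none))
  if (x$n_failed > 0) cat("Failed replicates:", x$n_failed, "\n")
  invisible(x)
}
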