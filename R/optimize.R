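#' Configuration for criterion-weight optimization
#'
#' Weights are box-bounded (\code{0.001 <= w_j <= 1}), constrained to a fixed
#' sum (\code{sum(w) = 12}), and must keep the score separation between the
#' two reference strains above a strict floor (\code{w' |x1 - x2| > 0.001}).
#' The objective adds \code{p * rank_gap} so that improving the positive
#' strain's rank relative to the negative strain is itself rewarded.
#'
#' @param p ranking-effect coefficient (default 0.010241)
#' @param lower_bound,upper_bound box bounds on each weight
#' @param sum_target required sum of the weights
#' @param separation_floor strict lower bound on \code{w' |x1 - x2|}
#' @param initial_mesh starting poll step size
#' @param expansion,contraction mesh multipliers on success/failure
#' @param max_mesh mesh ceiling; defaults to the box width, since larger
#'   steps are clipped by the bounds anyway and huge meshes only cost
#'   floating-point precision in the projection
#' @param mesh_tolerance stop when the mesh shrinks below this
#' @param max_iterations iteration cap
#' @return list of class \code{ffasc_opt_config}
#' @export
optimization_config <- function(p = 0.010241, lower_bound = 0.001,
                                upper_bound = 1, sum_target = 12,
                                separation_floor = 0.001,
                                initial_mesh = 0.25, expansion = 2,
                                contraction = 0.5,
                                max_mesh = upper_bound - lower_bound,
                                mesh_tolerance = 1e-6,
                                max_iterations = 2000) {
  stopifnot(p >= 0, lower_bound < upper_bound, initial_mesh > 0,
            expansion > 1, contraction > 0, contraction < 1,
            max_mesh >= initial_mesh, mesh_tolerance > 0, max_iterations >= 1)
  structure(list(p = p, lower_bound = lower_bound, upper_bound = upper_bound,
                 sum_target = sum_target, separation_floor = separation_floor,
                 initial_mesh = initial_mesh, expansion = expansion,
                 contraction = contraction, max_mesh = max_mesh,
                 mesh_tolerance = mesh_tolerance,
                 max_iterations = max_iterations),
            class = "ffasc_opt_config")
}

check_feasible_config <- function(config, m) {
  if (m * config$lower_bound > config$sum_target ||
      m * config$upper_bound < config$sum_target)
    ffasc_error("ffasc_infeasible_error", sprintf(
      "sum target %g unreachable with %d weights in [%g, %g]",
      config$sum_target, m, config$lower_bound, config$upper_bound))
}

#' Rank separation between the positive and negative reference strains
#'
#' Ranks all species by weighted score and returns
#' \code{rank(neg) - rank(pos)}: positive when the positive reference ranks
#' better (rank 1 is best).
#'
#' @param weights numeric weight vector
#' @param criteria species-by-OG criteria matrix
#' @param pos_id,neg_id reference species ids (rows of \code{criteria})
#' @return integer rank difference
#' @export
rank_gap <- function(weights, criteria, pos_id, neg_id) {
  ranking <- rank_species(score_species(criteria, weights), normalize = "none")
  r <- rank_of(ranking, c(pos_id, neg_id))
  r[2] - r[1]
}

#' Optimization objective for a candidate weight vector
#'
#' \code{w' |x_pos - x_neg| + p * rank_gap}: the weighted score separation of
#' the two reference strains plus the ranking-effect term.
#'
#' @param w numeric weight vector
#' @param x_pos,x_neg criteria vectors of the reference strains
#' @param p ranking-effect coefficient
#' @param rank_gap rank separation (see \code{\link{rank_gap}})
#' @return scalar objective value (maximized)
#' @export
objective_value <- function(w, x_pos, x_neg, p, rank_gap) {
  stopifnot(length(w) == length(x_pos), length(x_pos) == length(x_neg))
  sum(w * abs(x_pos - x_neg)) + p * rank_gap
}

#' Project a raw vector onto the feasible weight set
#'
#' Euclidean projection onto the intersection of the box
#' \code{[lower_bound, upper_bound]^m} and the hyperplane
#' \code{sum(w) = sum_target}, computed as the fixed point of clipping and
#' sum-restoring shifts (solved by bisection on the shift multiplier). A
#' feasible input is returned unchanged.
#'
#' @param w numeric vector of raw weights
#' @param config an \code{ffasc_opt_config}
#' @return feasible weight vector: in the box exactly, sum within 1e-9
#' @export
project_to_feasible <- function(w, config) {
  m <- length(w)
  check_feasible_config(config, m)
  lb <- config$lower_bound; ub <- config$upper_bound; s <- config$sum_target
  clip <- function(lambda) pmin(ub, pmax(lb, w + lambda))
  f <- function(lambda) sum(clip(lambda)) - s
  if (abs(f(0)) <= 1e-12) return(clip(0))
  lo <- min(lb - w); hi <- max(ub - w)   # f(lo) <= 0 <= f(hi)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-15) break
  }
  out <- clip((lo + hi) / 2)
  # polish the interior coordinates so the sum is met to strict tolerance
  free <- out > lb & out < ub
  if (any(free)) out[free] <- out[free] + (s - sum(out)) / sum(free)
  pmin(ub, pmax(lb, out))
}

#' Fit criterion weights by generalized pattern search
#'
#' Maximizes the score separation between a known good (positive) and a known
#' poor (negative) reference strain, plus a rank-separation reward, over the
#' feasible weight set. At each iteration the 2m coordinate directions scaled
#' by the current mesh are polled from the incumbent; each candidate is
#' projected onto the feasible set, candidates violating the strict
#' separation floor are rejected, and the poll is complete: the best
#' candidate is accepted if it improves the objective by more than a
#' relative sufficient-decrease margin (mesh expands), otherwise the mesh
#' contracts. Complete polling is used because the sum-constraint projection
#' couples all coordinates, so greedy first-improvement acceptance can stall
#' on negligible gains along unhelpful directions. Deterministic: no random
#' state is consumed.
#'
#' @param criteria species-by-OG criteria matrix (quantified values)
#' @param pos_id,neg_id positive / negative reference species ids
#' @param config an \code{ffasc_opt_config}
#' @param initial_weights optional starting vector (projected before use);
#'   default is the uniform feasible vector \code{sum_target / m}
#' @return list of class \code{ffasc_opt_result} with \code{weights} (named),
#'   \code{objective}, \code{iterations}, \code{feasible}, and \code{trace}
#'   (data.frame: iteration, objective, mesh, accepted)
#' @export
pattern_search_optimize <- function(criteria, pos_id, neg_id, config = optimization_config(),
                                    initial_weights = NULL) {
  stopifnot(pos_id != neg_id)
  if (!all(c(pos_id, neg_id) %in% rownames(criteria)))
    ffasc_error("ffasc_unknown_species_error",
                "reference species not found in criteria matrix")
  m <- ncol(criteria)
  check_feasible_config(config, m)
  dx <- abs(criteria[pos_id, ] - criteria[neg_id, ])
  sep_ok <- function(w) sum(w * dx) > config$separation_floor
  obj <- function(w)
    sum(w * dx) + config$p * rank_gap(w, criteria, pos_id, neg_id)

  w <- if (is.null(initial_weights)) rep(config$sum_target / m, m)
       else project_to_feasible(as.numeric(initial_weights), config)
  if (!sep_ok(w) && any(dx > 0))
    ffasc_error("ffasc_infeasible_error",
                "initial point violates the separation floor after projection")
  f <- obj(w)
  mesh <- config$initial_mesh
  trace <- vector("list", config$max_iterations)
  iter <- 0L
  while (mesh >= config$mesh_tolerance && iter < config$max_iterations) {
    iter <- iter + 1L
    best_f <- -Inf; best_w <- NULL
    for (j in seq_len(2L * m)) {
      coord <- ((j - 1L) %/% 2L) + 1L
      sgn <- if (j %% 2L == 1L) 1 else -1
      cand <- w
      cand[coord] <- cand[coord] + sgn * mesh
      cand <- project_to_feasible(cand, config)
      if (!sep_ok(cand) && any(dx > 0)) next
      fc <- obj(cand)
      if (fc > best_f) { best_f <- fc; best_w <- cand }
    }
    improved <- best_f > f + 1e-12 * (1 + abs(f))
    if (improved) { w <- best_w; f <- best_f }
    trace[[iter]] <- data.frame(iteration = iter, objective = f,
                                mesh = mesh, accepted = improved)
    mesh <- if (improved) min(mesh * config$expansion, config$max_mesh)
            else mesh * config$contraction
  }
  names(w) <- colnames(criteria)
  structure(list(weights = w, objective = f, iterations = iter,
                 feasible = abs(sum(w) - config$sum_target) <= 1e-9 &&
                   all(w >= config$lower_bound - 1e-12) &&
                   all(w <= config$upper_bound + 1e-12),
                 trace = do.call(rbind, trace[seq_len(iter)])),
            class = "ffasc_opt_result")
}

#' @export
print.ffasc_opt_result <- function(x, ...) {
  cat(sprintf("ffasc pattern-search result: objective %.6f after %d iterations (feasible: %s)\n",
              x$objective, x$iterations, x$feasible))
  invisible(x)
}

#' Write optimized weights to a two-column TSV (og_id, weight)
#' @param weights named numeric vector
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_weights <- function(weights, path) {
  utils::write.table(data.frame(og_id = names(weights),
                                weight = unname(weights)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$weight, df$og_id)
}
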