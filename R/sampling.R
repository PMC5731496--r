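#' Search parameters for the biased Monte-Carlo sampler
#'
#' @param max_iterations proposal budget (default 60000).
#' @param rotation_limit half-width of the uniform dihedral perturbation in
#'   degrees; moves are drawn from (-rotation_limit, +rotation_limit).
#' @param scaling_factor_a positive scaling factor \code{a} of the Metropolis
#'   acceptance rule.
#' @param energy_threshold conformations with energy at or above this value
#'   are discarded before the acceptance rule. \code{NULL} resolves at run
#'   time to \code{max(E(start), E(goal)) + 10}.
#' @param skip_angle_tolerance pseudo-dihedrals whose absolute difference to
#'   the goal is at most this many degrees are never selected for rotation.
#' @param goal_rmsd_stop stop once some pool member is within this RMSD (A)
#'   of the goal.
#' @param parent_policy \code{"uniform"} draws the parent uniformly from the
#'   pool; \code{"goal_biased"} weights members by 1/(rmsd_to_goal + 0.1 A);
#'   \code{"greedy"} always expands the current best.
#' @param seed integer seed making the whole search reproducible.
#' @return a \code{search_params} list.
#' @export
search_params <- function(max_iterations = 60000L, rotation_limit = 5,
                          scaling_factor_a = 1.0, energy_threshold = NULL,
                          skip_angle_tolerance = 1, goal_rmsd_stop = 1.5,
                          parent_policy = c("uniform", "goal_biased", "greedy"),
                          seed = 1L) {
  stopifnot(max_iterations >= 1, rotation_limit > 0, scaling_factor_a > 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 rotation_limit = rotation_limit,
                 scaling_factor_a = scaling_factor_a,
                 energy_threshold = energy_threshold,
                 skip_angle_tolerance = skip_angle_tolerance,
                 goal_rmsd_stop = goal_rmsd_stop,
                 parent_policy = match.arg(parent_policy),
                 seed = as.integer(seed)),
            class = "search_params")
}

wrap_angle_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)  # in [0, 180]
}

#' Select a rotatable virtual bond, biased toward the goal
#'
#' Bond i is chosen with probability proportional to the absolute circular
#' difference between the current i-th pseudo-dihedral and its counterpart
#' in the goal, restricted to bonds whose difference exceeds the tolerance
#' (near-converged angles are skipped).
#'
#' @param current,goal \code{calpha} structures sharing topology.
#' @param tol skip tolerance in degrees.
#' @return the selected bond index, or \code{NA_integer_} when every angle is
#'   within tolerance (convergence signal).
#' @export
select_bond <- function(current, goal, tol = 1) {
  delta <- wrap_angle_diff(pseudo_dihedrals(current), pseudo_dihedrals(goal))
  cand <- which(delta > tol)
  if (length(cand) == 0L) return(NA_integer_)
  if (length(cand) == 1L) return(cand)
  sample(cand, 1L, prob = delta[cand])
}

#' Metropolis-like acceptance rule of the biased search
#'
#' A proposal is accepted when it moves closer to the goal
#' (\code{rmsd_new < rmsd_parent}), or otherwise when
#' \code{log(r) < -(rmsd_new - rmsd_parent) / (a * rmsd_new)} for a uniform
#' draw \code{r}. A proposal with \code{rmsd_new = 0} has reached the goal
#' and is always accepted.
#'
#' @param rmsd_new,rmsd_parent RMSD to the goal of the proposal and of its
#'   parent, in Angstrom.
#' @param a positive scaling factor.
#' @param r uniform(0,1) draw.
#' @return logical.
#' @export
accept_move <- function(rmsd_new, rmsd_parent, a = 1, r) {
  if (a <= 0) stop("scaling factor a must be positive")
  stopifnot(rmsd_new >= 0, rmsd_parent >= 0, r > 0, r < 1)
  if (rmsd_new == 0) return(TRUE)
  if (rmsd_new < rmsd_parent) return(TRUE)
  log(r) < -(rmsd_new - rmsd_parent) / (a * rmsd_new)
}

#' Choose a parent conformation from the pool
#'
#' @param rmsd_to_goal numeric vector of pool RMSDs to the goal.
#' @param policy one of \code{"uniform"}, \code{"goal_biased"},
#'   \code{"greedy"}.
#' @return index into the pool.
#' @export
parent_selection <- function(rmsd_to_goal,
                             policy = c("uniform", "goal_biased", "greedy")) {
  policy <- match.arg(policy)
  n <- length(rmsd_to_goal)
  if (n == 1L) return(1L)
  switch(policy,
         uniform = sample.int(n, 1L),
         goal_biased = sample.int(n, 1L, prob = 1 / (rmsd_to_goal + 0.1)),
         greedy = which.min(rmsd_to_goal))
}

#' Biased Monte-Carlo conformational search
#'
#' Grows a pool of accepted conformations from \code{start} toward
#' \code{goal}. Each iteration draws a parent from the pool, selects a
#' pseudo-dihedral biased toward angles that still differ from the goal,
#' perturbs it by a uniform rotation within \code{rotation_limit} degrees,
#' discards the proposal if its energy reaches the threshold, and otherwise
#' applies the acceptance rule on the RMSD to the goal. The result is a
#' tree-structured pathway rooted at the start conformation.
#'
#' @param start,goal \code{calpha} structures with identical residue
#'   numbering.
#' @param params a \code{\link{search_params}} object.
#' @param energy_fn energy function \code{calpha -> numeric}; defaults to
#'   \code{\link{calpha_energy}}.
#' @return an \code{mc_trajectory}: list with \code{conformations} (list of
#'   3N vectors), \code{parents}, \code{energies}, \code{rmsd_to_goal},
#'   \code{template}, \code{iterations}, \code{accepted}, \code{params}.
#' @export
run_search <- function(start, goal, params = search_params(),
                       energy_fn = calpha_energy) {
  if (!identical(start$resno, goal$resno))
    stop("start and goal must share residue topology")
  set.seed(params$seed)
  e_start <- energy_fn(start)
  thr <- params$energy_threshold
  if (is.null(thr)) thr <- max(e_start, energy_fn(goal)) + 10
  goal_dih <- pseudo_dihedrals(goal)

  pool <- list(start)
  parents <- 0L
  energies <- e_start
  rmsds <- kabsch_rmsd(start, goal)
  accepted <- 0L
  iter <- 0L

  if (rmsds[1] <= params$goal_rmsd_stop ||
      all(wrap_angle_diff(pseudo_dihedrals(start), goal_dih) <=
            params$skip_angle_tolerance)) {
    return(new_trajectory(pool, parents, energies, rmsds, start, 0L, 0L, params, thr))
  }

  while (iter < params$max_iterations) {
    iter <- iter + 1L
    pi <- parent_selection(rmsds, params$parent_policy)
    parent <- pool[[pi]]
    delta <- wrap_angle_diff(pseudo_dihedrals(parent), goal_dih)
    cand <- which(delta > params$skip_angle_tolerance)
    if (length(cand) == 0L) next  # this parent has converged angles
    bond <- if (length(cand) == 1L) cand else sample(cand, 1L, prob = delta[cand])
    move <- stats::runif(1, -params$rotation_limit, params$rotation_limit)
    prop <- apply_dihedral_rotation(parent, bond, move)
    e <- energy_fn(prop)
    if (e >= thr) next
    rmsd_new <- kabsch_rmsd(prop, goal)
    if (accept_move(rmsd_new, rmsds[pi], params$scaling_factor_a, stats::runif(1))) {
      pool[[length(pool) + 1L]] <- prop
      parents <- c(parents, pi)
      energies <- c(energies, e)
      rmsds <- c(rmsds, rmsd_new)
      accepted <- accepted + 1L
      if (rmsd_new <= params$goal_rmsd_stop) break
    }
  }
  new_trajectory(pool, parents, energies, rmsds, start, iter, accepted, params, thr)
}

new_trajectory <- function(pool, parents, energies, rmsds, template,
                           iterations, accepted, params, threshold) {
  structure(list(conformations = lapply(pool, as_conformation_vector),
                 parents = parents, energies = energies,
                 rmsd_to_goal = rmsds, template = template,
                 iterations = iterations, accepted = accepted,
                 params = params, energy_threshold = threshold),
            class = "mc_trajectory")
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cat(sprintf(paste0("Monte-Carlo pathway: %d conformations ",
                     "(%d proposals, acceptance %.1f%%)\n"),
              length(x$conformations), x$iterations,
              if (x$iterations > 0) 100 * x$accepted / x$iterations else 0))
  cat(sprintf("  RMSD to goal: start %.2f A, best %.2f A\n",
              x$rmsd_to_goal[1], min(x$rmsd_to_goal)))
  invisible(x)
}

#' @export
summary.mc_trajectory <- function(object, ...) {
  data.frame(model = seq_along(object$conformations),
             parent = object$parents,
             energy = object$energies,
             rmsd_to_goal = object$rmsd_to_goal)
}

#' Conformation matrix of a trajectory
#'
#' @param traj an \code{mc_trajectory}.
#' @return numeric M x 3N matrix, one conformation vector per row.
#' @export
trajectory_matrix <- function(traj) {
  do.call(rbind, traj$conformations)
}

#' Extract one conformation of a trajectory as a structure
#'
#' @param traj an \code{mc_trajectory}.
#' @param i model index.
#' @return a \code{calpha} structure.
#' @export
trajectory_structure <- function(traj, i) {
  conformation_to_structure(traj$conformations[[i]], traj$template)
}

#' Write a trajectory as multi-model PDB plus per-model CSV
#'
#' @param traj an \code{mc_trajectory}.
#' @param pdb_path path of the multi-model PDB to write.
#' @param csv_path optional path of a CSV with model, parent, energy and
#'   rmsd_to_goal columns.
#' @return \code{pdb_path}, invisibly.
#' @export
write_trajectory <- function(traj, pdb_path, csv_path = NULL) {
  models <- lapply(seq_along(traj$conformations),
                   function(i) trajectory_structure(traj, i))
  write_calpha_pdb(models, pdb_path)
  if (!is.null(csv_path))
    utils::write.csv(summary(traj), csv_path, row.names = FALSE)
  invisible(pdb_path)
}
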