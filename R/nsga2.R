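# NSGA-II (Deb et al. 2002): fast non-dominated sorting, crowding
# distance, binary tournament, SBX crossover, polynomial mutation,
# elitist (mu + lambda) replacement. Generic engine; the material
# identification wrapper lives in fit.R.

.BIG_OBJ <- 1e30

# front rank per row of the objective matrix (1 = non-dominated)
nondominated_rank <- function(obj) {
  n <- nrow(obj); m <- ncol(obj)
  leq <- matrix(TRUE, n, n); lt <- matrix(FALSE, n, n)
  for (k in seq_len(m)) {
    ok <- outer(obj[, k], obj[, k], `<=`)
    leq <- leq & ok
    lt <- lt | outer(obj[, k], obj[, k], `<`)
  }
  dom <- leq & lt              # dom[i, j]: i dominates j
  ndom <- colSums(dom)
  rank <- integer(n)
  cur <- 1L
  remaining <- ndom
  alive <- rep(TRUE, n)
  while (any(alive)) {
    front <- which(alive & remaining == 0L)
    if (length(front) == 0L) stop("non-dominated sort failed")
    rank[front] <- cur
    alive[front] <- FALSE
    if (any(alive))
      remaining <- remaining - colSums(dom[front, , drop = FALSE])
    cur <- cur + 1L
  }
  rank
}

crowding_distance <- function(obj) {
  n <- nrow(obj)
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(obj))) {
    o <- order(obj[, k])
    rng <- obj[o[n], k] - obj[o[1], k]
    d[o[c(1L, n)]] <- Inf
    if (rng > 0)
      d[o[2:(n - 1L)]] <- d[o[2:(n - 1L)]] +
        (obj[o[3:n], k] - obj[o[1:(n - 2L)], k]) / rng
  }
  d
}

.tournament <- function(rank, crowd, n_out) {
  n <- length(rank)
  a <- sample.int(n, n_out, replace = TRUE)
  b <- sample.int(n, n_out, replace = TRUE)
  pick_a <- rank[a] < rank[b] |
    (rank[a] == rank[b] & crowd[a] > crowd[b]) |
    (rank[a] == rank[b] & crowd[a] == crowd[b] & a <= b)
  ifelse(pick_a, a, b)
}

.sbx_pair <- function(p1, p2, lower, upper, pc, eta) {
  c1 <- p1; c2 <- p2
  if (stats::runif(1) <= pc) {
    for (j in seq_along(p1)) {
      if (stats::runif(1) <= 0.5 && abs(p1[j] - p2[j]) > 1e-14) {
        u <- stats::runif(1)
        bq <- if (u <= 0.5) (2 * u)^(1 / (eta + 1))
              else (1 / (2 * (1 - u)))^(1 / (eta + 1))
        c1[j] <- 0.5 * ((1 + bq) * p1[j] + (1 - bq) * p2[j])
        c2[j] <- 0.5 * ((1 - bq) * p1[j] + (1 + bq) * p2[j])
      }
    }
  }
  rbind(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

.poly_mutate <- function(x, lower, upper, pm, eta) {
  for (j in seq_along(x)) {
    if (stats::runif(1) <= pm) {
      rng <- upper[j] - lower[j]
      d1 <- (x[j] - lower[j]) / rng
      d2 <- (upper[j] - x[j]) / rng
      u <- stats::runif(1)
      dq <- if (u < 0.5)
        (2 * u + (1 - 2 * u) * (1 - d1)^(eta + 1))^(1 / (eta + 1)) - 1
      else
        1 - (2 * (1 - u) + 2 * (u - 0.5) * (1 - d2)^(eta + 1))^(1 / (eta + 1))
      x[j] <- min(max(x[j] + dq * rng, lower[j]), upper[j])
    }
  }
  x
}

.sanitize_obj <- function(obj, n_expected = NULL) {
  obj <- as.matrix(obj)
  if (!is.null(n_expected) && nrow(obj) != n_expected)
    stop("objective function must return one row per candidate",
         call. = FALSE)
  bad <- !is.finite(obj)
  if (any(bad)) {
    rows <- unique(which(bad, arr.ind = TRUE)[, 1])
    obj[rows, ] <- .BIG_OBJ
  }
  obj
}

#' Multi-objective minimization by NSGA-II
#'
#' Elitist non-dominated sorting genetic algorithm with simulated binary
#' crossover and polynomial mutation. The individual with the smallest
#' equally weighted objective sum is explicitly preserved across
#' generations, so the scalarized generation-best trace is non-increasing.
#' Candidates whose objectives evaluate non-finite are assigned a large
#' penalty on every objective; an all-non-finite initial population is an
#' error.
#'
#' @param fn vectorized objective: takes an `n x d` matrix of candidates,
#'   returns an `n x m` matrix of objective values (minimized).
#' @param lower,upper numeric bounds vectors of length `d`.
#' @param pop_size even population size >= 4.
#' @param generations number of generations.
#' @param seed integer RNG seed.
#' @param pc,pm crossover and per-variable mutation probabilities.
#' @param eta_c,eta_m SBX and mutation distribution indices.
#' @param init optional initial population matrix (rows clamped to
#'   bounds); by default a Sobol point set over the bounds box.
#' @param local_search optional Lamarckian refinement operator: a
#'   deterministic function mapping a candidate vector to an improved
#'   candidate (e.g. a few hundred Nelder-Mead iterations on the
#'   objective sum). Applied to the scalar-best member every
#'   `refine_every` generations and after the final generation; the
#'   refined candidate replaces it only when it improves the sum.
#'   Coordinate-wise genetic operators alone stall in the strongly
#'   correlated, ill-conditioned valleys typical of material
#'   identification, which is why the hybrid exists.
#' @param refine_every generations between local refinements.
#' @return List with `par` (final population), `objectives`, `rank`
#'   (non-domination front per member), `pareto` (logical, front 1),
#'   `best` (row index of minimum objective sum), `trace` (per-generation
#'   minimum objective sum).
#' @export
nsga2 <- function(fn, lower, upper, pop_size = 100L, generations = 100L,
                  seed = 1L, pc = 0.9, pm = 1 / length(lower),
                  eta_c = 15, eta_m = 20, init = NULL,
                  local_search = NULL, refine_every = 10L) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(lower < upper),
            pop_size >= 4L, pop_size %% 2L == 0L, generations >= 1L)
  set.seed(as.integer(seed))
  if (is.null(init)) {
    u <- sobol_points(pop_size, d)
    pop <- sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
  } else {
    stopifnot(ncol(init) == d)
    pop <- sweep(sweep(init, 2, lower, pmax), 2, upper, pmin)
    if (nrow(pop) != pop_size)
      pop <- pop[rep_len(seq_len(nrow(pop)), pop_size), , drop = FALSE]
  }
  obj <- .sanitize_obj(fn(pop), pop_size)
  if (all(obj >= .BIG_OBJ))
    stop(paste("all initial candidates produced non-finite objectives;",
               "check parameter bounds"), call. = FALSE)
  rank <- nondominated_rank(obj)
  crowd <- numeric(pop_size)
  for (f in unique(rank)) {
    i <- rank == f
    crowd[i] <- crowding_distance(obj[i, , drop = FALSE])
  }
  trace <- numeric(generations)
  for (gen in seq_len(generations)) {
    parents <- .tournament(rank, crowd, pop_size)
    children <- matrix(0, pop_size, d)
    for (i in seq_len(pop_size / 2L)) {
      pr <- .sbx_pair(pop[parents[2 * i - 1L], ], pop[parents[2 * i], ],
                      lower, upper, pc, eta_c)
      children[2 * i - 1L, ] <- .poly_mutate(pr[1, ], lower, upper, pm, eta_m)
      children[2 * i, ] <- .poly_mutate(pr[2, ], lower, upper, pm, eta_m)
    }
    cobj <- .sanitize_obj(fn(children), pop_size)
    allp <- rbind(pop, children)
    allo <- rbind(obj, cobj)
    arank <- nondominated_rank(allo)
    sel <- integer(0)
    f <- 1L
    while (length(sel) < pop_size) {
      front <- which(arank == f)
      if (length(sel) + length(front) <= pop_size) {
        sel <- c(sel, front)
      } else {
        cd <- crowding_distance(allo[front, , drop = FALSE])
        need <- pop_size - length(sel)
        keep <- front[order(cd, decreasing = TRUE)[seq_len(need)]]
        sel <- c(sel, keep)
      }
      f <- f + 1L
    }
    # guarantee the scalar-best member survives (monotone trace)
    best_all <- which.min(rowSums(allo))
    if (!(best_all %in% sel)) sel[length(sel)] <- best_all
    pop <- allp[sel, , drop = FALSE]
    obj <- allo[sel, , drop = FALSE]
    if (!is.null(local_search) &&
        (gen %% refine_every == 0L || gen == generations)) {
      ib <- which.min(rowSums(obj))
      xr <- pmin(pmax(local_search(pop[ib, ]), lower), upper)
      or <- .sanitize_obj(fn(matrix(xr, nrow = 1)), 1L)
      if (sum(or) < sum(obj[ib, ])) {
        pop[ib, ] <- xr
        obj[ib, ] <- or
      }
    }
    rank <- nondominated_rank(obj)
    crowd <- numeric(pop_size)
    for (fr in unique(rank)) {
      i <- rank == fr
      crowd[i] <- crowding_distance(obj[i, , drop = FALSE])
    }
    trace[gen] <- min(rowSums(obj))
  }
  list(par = pop, objectives = obj, rank = rank, pareto = rank == 1L,
       best = which.min(rowSums(obj)), trace = trace)
}
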