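# ---- (MI)LP backend ---------------------------------------------------------
# The LP relaxation and the exact ILP are formulated here; the numerical
# solve is delegated to HiGHS through SciPy's milp interface, driven by a
# batch script shipped with the package and executed with the `python`
# interpreter on PATH (configurable via options(zcnt.python = ...)).

.python_bin <- function() {
  py <- getOption("zcnt.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter found for the (MI)LP backend; ",
                        "set options(zcnt.python = ...)")
  py
}

# problems: list of lists with obj, Ai, Aj, Av, rhs, lb, ub, integrality
.milp_solve <- function(problems) {
  script <- system.file("python", "milp_solve.py", package = "zcnt",
                        mustWork = TRUE)
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(problems, fin, auto_unbox = FALSE, digits = NA)
  status <- system2(.python_bin(), c(shQuote(script), shQuote(fin),
                                     shQuote(fout)),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout) || length(attr(status, "status")))
    stop("MILP backend failed: ", paste(status, collapse = "\n"))
  res <- jsonlite::fromJSON(fout, simplifyVector = FALSE)
  for (r in res) if (!isTRUE(r$success))
    stop("MILP backend returned solver status ", r$status, ": ", r$message)
  res
}

# Build the small-parsimony model for one chromosome segment.
#
# Variables: x[u, j] for internal vertices u and segment coordinates j,
# then e+ and e- slack pairs, one per (edge, coordinate), splitting the
# absolute difference along each edge. Equalities: per edge/coordinate
# difference rows and one balancing row per internal vertex. Leaf labels
# enter as constants. Bounds on x: [min leaf delta - slack, max leaf delta
# + slack] per coordinate.
.sp_model <- function(tree, Qseg, slack, integer) {
  ntip <- ape::Ntip(tree)
  N <- ntip + tree$Nnode
  L <- ncol(Qseg)
  internal <- (ntip + 1L):N
  xid <- matrix(0L, N, L)
  xid[internal, ] <- seq_len(length(internal) * L)
  nx <- length(internal) * L
  E <- tree$edge
  nE <- nrow(E)
  ne <- nE * L
  nvar <- nx + 2L * ne
  lo_j <- apply(Qseg, 2L, min) - slack
  hi_j <- apply(Qseg, 2L, max) + slack
  lb <- numeric(nvar); ub <- numeric(nvar)
  for (k in seq_along(internal)) {
    idx <- xid[internal[k], ]
    lb[idx] <- lo_j; ub[idx] <- hi_j
  }
  lb[(nx + 1L):nvar] <- 0; ub[(nx + 1L):nvar] <- Inf
  obj <- c(numeric(nx), rep(1, 2L * ne))
  Ai <- Aj <- Av <- list(); rhs <- numeric(0); row <- 0L
  add <- function(i, j, v) { Ai[[length(Ai) + 1L]] <<- i
    Aj[[length(Aj) + 1L]] <<- j; Av[[length(Av) + 1L]] <<- v }
  for (k in seq_len(nE)) {
    u <- E[k, 1L]; v <- E[k, 2L]
    for (j in seq_len(L)) {
      row <- row + 1L
      r <- 0
      if (u > ntip) add(row, xid[u, j], 1) else r <- r - Qseg[u, j]
      if (v > ntip) add(row, xid[v, j], -1) else r <- r + Qseg[v, j]
      ep <- nx + (k - 1L) * L + j
      em <- nx + ne + (k - 1L) * L + j
      add(row, ep, -1); add(row, em, 1)
      rhs <- c(rhs, r)
    }
  }
  for (u in internal) {
    row <- row + 1L
    add(row, xid[u, seq_len(L)], rep(1, L))
    rhs <- c(rhs, 0)
  }
  # expand triplets (add() may push vectors)
  len <- vapply(Aj, length, integer(1))
  Ai <- unlist(mapply(function(i, l) rep(i, l), Ai, len, SIMPLIFY = FALSE))
  Aj <- unlist(Aj); Av <- unlist(Av)
  integrality <- c(rep(if (integer) 1L else 0L, nx), rep(0L, 2L * ne))
  list(obj = obj, Ai = Ai, Aj = Aj, Av = Av, rhs = rhs, lb = lb, ub = ub,
       integrality = integrality, nx = nx, xid = xid, internal = internal,
       L = L)
}

# Solve the balanced small parsimony problem (integer = TRUE for the exact
# ILP, FALSE for the LP relaxation), expanding the label box until no bound
# is active.
.sp_solve <- function(tree, cnm, baseline, integer, slack = NULL,
                      max_expand = 5L) {
  tree <- .prep_tree(tree)
  Q <- .leaf_delta(tree, cnm, baseline)
  lay <- .seg_layout(cnm$bins)
  if (is.null(slack)) {
    ub <- unbalanced_small_parsimony(tree, cnm, baseline)
    slack <- max(1, max(abs(vertex_discrepancy(ub$labeling))))
  }
  ntip <- ape::Ntip(tree)
  N <- ntip + tree$Nnode
  lab <- matrix(NA_real_, N, lay$D)
  lab[seq_len(ntip), ] <- Q
  total <- 0
  for (i in seq_along(lay$chroms)) {
    cols <- lay$d_start[i] + seq_len(lay$d_per_chrom[i]) - 1L
    Qseg <- Q[, cols, drop = FALSE]
    s <- slack
    for (trial in seq_len(max_expand)) {
      mod <- .sp_model(tree, Qseg, s, integer)
      res <- .milp_solve(list(mod))[[1L]]
      x <- unlist(res$x)
      vals <- matrix(NA_real_, N, mod$L)
      for (u in mod$internal) vals[u, ] <- x[mod$xid[u, ]]
      at_bound <- FALSE
      for (u in mod$internal) {
        lo_j <- apply(Qseg, 2L, min) - s
        hi_j <- apply(Qseg, 2L, max) + s
        if (any(vals[u, ] <= lo_j + 1e-6) || any(vals[u, ] >= hi_j - 1e-6))
          at_bound <- TRUE
      }
      if (!at_bound || trial == max_expand) break
      s <- 2 * s + 1
    }
    lab[, cols] <- rbind(Qseg, vals[(ntip + 1L):N, , drop = FALSE])
    total <- total + res$fun
  }
  lab <- structure(lab, seg = lay$seg, space = "delta")
  list(tree = tree, labeling = lab, score_l1 = total)
}

#' LP relaxation of ZCNT small parsimony
#'
#' Minimizes the summed per-edge L1 distance subject to leaf agreement and
#' per-chromosome balancing with the integrality requirement dropped,
#' using the standard absolute-value split into non-negative slack
#' variables. The fractional optimum is sandwiched between the unbalanced
#' optimum and the exact integer optimum.
#'
#' @inheritParams unbalanced_small_parsimony
#' @param slack initial half-width added to the per-coordinate leaf range
#'   to bound ancestral labels; expanded automatically if a bound is active
#'   at the optimum. Defaults to the maximum absolute discrepancy of the
#'   unbalanced solution.
#' @return A \code{zcnt_parsimony} result (method \code{"lp"}); the score
#'   is the fractional LP value and the labeling may be fractional.
#' @export
lp_relaxation_small_parsimony <- function(tree, cnm, baseline = 2L,
                                          slack = NULL) {
  s <- .sp_solve(tree, cnm, baseline, integer = FALSE, slack = slack)
  .parsimony_result("lp", s$tree, s$labeling, s$score_l1)
}

#' Exact ZCNT small parsimony by integer linear programming
#'
#' Solves the ZCNT small parsimony problem exactly: integer ancestral delta
#' profiles satisfying the per-chromosome balancing condition, minimizing
#' the summed per-edge L1 distance. Suitable for moderately sized
#' instances; the 2-approximation [two_approx_small_parsimony()] scales to
#' large ones.
#'
#' @inheritParams lp_relaxation_small_parsimony
#' @return A \code{zcnt_parsimony} result (method \code{"ilp"}) whose
#'   integer labeling achieves the returned score.
#' @export
exact_small_parsimony_ilp <- function(tree, cnm, baseline = 2L,
                                      slack = NULL) {
  s <- .sp_solve(tree, cnm, baseline, integer = TRUE, slack = slack)
  lab <- structure(round(s$labeling), seg = attr(s$labeling, "seg"),
                   space = "delta")
  sc <- parsimony_score(s$tree, lab)
  if (abs(sc$score_l1 - s$score_l1) > 1e-6)
    stop("ILP labeling does not reproduce the reported score")
  .parsimony_result("ilp", s$tree, lab, sc$score_l1)
}
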