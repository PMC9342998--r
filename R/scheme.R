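#' Define a kinetic scheme
#'
#' A kinetic scheme is a finite-state continuous-time Markov model of a
#' single channel: a set of conformational/binding states connected by
#' rate parameters. Binding edges (`ligand = 1`) have pseudo-first-order
#' rates, i.e. their rate-matrix entry is `rate * L` with `L` the ligand
#' concentration in micromolar, so binding parameters carry units of
#' uM^-1 s^-1 and all other rates s^-1.
#'
#' @param states Character vector of state names. States are indexed
#'   1..M in the order given; user-facing configuration is 1-based.
#' @param edges A data frame with columns `from`, `to` (state names),
#'   `param` (rate parameter name) and `ligand` (0 or 1; 1 marks a
#'   binding step).
#' @param conducting Numeric vector (length M) of mean single-channel
#'   current multipliers per state (0 or 1 here).
#' @param bound_ligands Integer vector (length M) counting ligands bound
#'   in each state; must differ by exactly 1 across any binding edge.
#' @param loops Optional list of directed cycles for microscopic
#'   reversibility. Each element is a list with fields `target` (the
#'   rate completed by the hierarchical prior), `numer` and `denom`
#'   (character vectors of parameter names): at strict microscopic
#'   reversibility `target = prod(numer) / prod(denom)`.
#' @param name Optional scheme name used in printing and file metadata.
#' @return An object of class `kinetic_scheme`.
#' @examples
#' sch <- scheme_ccco()
#' sch$edges
#' @export
kinetic_scheme <- function(states, edges, conducting, bound_ligands,
                           loops = list(), name = "scheme") {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("from", "to", "param", "ligand") %in% names(edges)))
  M <- length(states)
  if (anyDuplicated(states)) stop("duplicate state names")
  if (!all(edges$from %in% states) || !all(edges$to %in% states))
    stop("edge references an undeclared state")
  if (!all(edges$ligand %in% c(0, 1)))
    stop("ligand order must be 0 or 1")
  if (length(conducting) != M || length(bound_ligands) != M)
    stop("conducting and bound_ligands must have one entry per state")
  bi <- match(edges$from, states)
  bj <- match(edges$to, states)
  bad <- edges$ligand == 1 &
    abs(bound_ligands[bj] - bound_ligands[bi]) != 1
  if (any(bad))
    stop("bound_ligands must differ by exactly 1 across binding edges: ",
         paste(edges$param[bad], collapse = ", "))
  pars <- unique(edges$param)
  for (lp in loops) {
    refs <- c(lp$target, lp$numer, lp$denom)
    if (!all(refs %in% pars))
      stop("loop references undeclared parameter: ",
           paste(setdiff(refs, pars), collapse = ", "))
  }
  structure(
    list(states = states, edges = edges,
         conducting = as.numeric(conducting),
         bound_ligands = as.integer(bound_ligands),
         loops = loops, name = name),
    class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme> ", x$name, ": ", length(x$states), " states, ",
      nrow(x$edges), " edges, ", length(x$loops), " loop(s)\n", sep = "")
  cat("  states:", paste0(x$states, ifelse(x$conducting > 0, "*", ""),
                          collapse = " "), " (* conducting)\n")
  invisible(x)
}

#' Number of states of a scheme
#' @param scheme A `kinetic_scheme`.
#' @return Integer number of states.
#' @export
n_states <- function(scheme) length(scheme$states)

#' Rate parameter names of a scheme
#' @param scheme A `kinetic_scheme`.
#' @return Character vector of parameter names in edge order.
#' @export
rate_names <- function(scheme) unique(scheme$edges$param)

#' The four-state CCCO scheme (C1 = C2 = C3 = O4)
#'
#' Two sequential ligand-binding steps followed by one opening step;
#' only O4 conducts; C2 carries one bound ligand, C3 and O4 two.
#' @return A `kinetic_scheme`.
#' @export
scheme_ccco <- function() {
  kinetic_scheme(
    states = c("C1", "C2", "C3", "O4"),
    edges = tibble::tribble(
      ~from, ~to,  ~param,   ~ligand,
      "C1",  "C2", "kon1",   1,
      "C2",  "C1", "koff1",  0,
      "C2",  "C3", "kon2",   1,
      "C3",  "C2", "koff2",  0,
      "C3",  "O4", "kopen",  0,
      "O4",  "C3", "kclose", 0),
    conducting = c(0, 0, 0, 1),
    bound_ligands = c(0, 1, 2, 2),
    name = "CCCO")
}

#' Canonical rate set for the CCCO scheme
#'
#' The package's documented default parameterization (binding rates in
#' uM^-1 s^-1, all others s^-1). Dissociation constants are 2 uM and
#' 10 uM for the two binding steps and the open/closed equilibrium is 3,
#' placing the activation midpoint inside the standard 0.0625-64 uM
#' concentration ladder.
#' @return Named numeric vector of rates.
#' @export
ccco_rates <- function() {
  c(kon1 = 20, koff1 = 40, kon2 = 10, koff2 = 100,
    kopen = 150, kclose = 50)
}

#' Five-state scheme with two open states
#'
#' Two binding steps along C1 = C2 = C3 plus opening transitions from
#' each liganded closed state (C2 = O4, C3 = O5).
#' @return A `kinetic_scheme`.
#' @export
scheme_5s2o <- function() {
  kinetic_scheme(
    states = c("C1", "C2", "C3", "O4", "O5"),
    edges = tibble::tribble(
      ~from, ~to,  ~param,    ~ligand,
      "C1",  "C2", "kon1",    1,
      "C2",  "C1", "koff1",   0,
      "C2",  "C3", "kon2",    1,
      "C3",  "C2", "koff2",   0,
      "C2",  "O4", "kopen1",  0,
      "O4",  "C2", "kclose1", 0,
      "C3",  "O5", "kopen2",  0,
      "O5",  "C3", "kclose2", 0),
    conducting = c(0, 0, 0, 1, 1),
    bound_ligands = c(0, 1, 2, 1, 2),
    name = "5-state-2-open")
}

#' Six-state scheme with one open state and a loop
#'
#' The main activation path C1 = C2 = C3 = O4 (two bindings, one
#' opening) plus a parallel flip path C2 = C5 = C6 = C3 closing a
#' four-state cycle (C2, C3, C6, C5). The declared loop feeds the
#' hierarchical microscopic-reversibility prior, which constrains the
#' clockwise and anticlockwise rate products around the cycle to agree
#' within a narrow band (the completed rate is `ku32`).
#' @return A `kinetic_scheme`.
#' @export
scheme_6s1o_loop <- function() {
  kinetic_scheme(
    states = c("C1", "C2", "C3", "O4", "C5", "C6"),
    edges = tibble::tribble(
      ~from, ~to,  ~param,   ~ligand,
      "C1",  "C2", "kon1",   1,
      "C2",  "C1", "koff1",  0,
      "C2",  "C3", "kb23",   1,
      "C3",  "C2", "ku32",   0,
      "C3",  "O4", "kopen",  0,
      "O4",  "C3", "kclose", 0,
      "C2",  "C5", "kc25",   0,
      "C5",  "C2", "kc52",   0,
      "C5",  "C6", "kb56",   1,
      "C6",  "C5", "ku65",   0,
      "C6",  "C3", "kc63",   0,
      "C3",  "C6", "kc36",   0),
    conducting = c(0, 0, 0, 1, 0, 0),
    bound_ligands = c(0, 1, 2, 2, 1, 2),
    loops = list(list(
      # cycle C2 -> C3 -> C6 -> C5 -> C2: clockwise product
      # kb23 * kc36 * ku65 * kc52, anticlockwise kc25 * kb56 * kc63 * ku32.
      target = "ku32",
      numer = c("kb23", "kc36", "ku65", "kc52"),
      denom = c("kc25", "kb56", "kc63"))),
    name = "6-state-1-open-loop")
}

#' Build the rate matrix of a scheme at a ligand concentration
#'
#' Off-diagonal entry `K[i, j]` is the transition rate from state j to
#' state i in s^-1; binding edges are scaled by the ligand concentration
#' (pseudo-first-order kinetics); diagonal entries close each column to
#' zero so that `K` is a proper generator.
#'
#' @param scheme A `kinetic_scheme`.
#' @param rates Named numeric vector or list mapping every rate
#'   parameter of the scheme to a non-negative value.
#' @param conc Ligand concentration in uM (>= 0).
#' @return M x M rate matrix with `dimnames` set to the state names.
#' @examples
#' K <- build_rate_matrix(scheme_ccco(), ccco_rates(), conc = 64)
#' colSums(K)  # zero
#' @export
build_rate_matrix <- function(scheme, rates, conc) {
  rates <- unlist(rates)
  stopifnot(is.numeric(conc), length(conc) == 1, conc >= 0)
  need <- rate_names(scheme)
  miss <- setdiff(need, names(rates))
  if (length(miss))
    stop("missing rate parameter(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(rates[need])) || any(rates[need] < 0))
    stop("rates must be finite and non-negative")
  M <- n_states(scheme)
  K <- matrix(0, M, M, dimnames = list(scheme$states, scheme$states))
  e <- scheme$edges
  i <- match(e$to, scheme$states)
  j <- match(e$from, scheme$states)
  val <- rates[e$param] * ifelse(e$ligand == 1, conc, 1)
  for (k in seq_len(nrow(e))) K[i[k], j[k]] <- K[i[k], j[k]] + val[k]
  diag(K) <- diag(K) - colSums(K)
  K
}

#' Discrete-time transition matrix over a step dt
#'
#' `T = expm(K * dt)`, the column-stochastic single-channel transition
#' matrix (entry `[i, j]` = probability of being in state i after dt
#' given state j). Uses scaling-and-squaring with Pade approximation
#' (via `Matrix::expm`), which stays stable for the stiff generators
#' arising at high ligand concentration.
#'
#' @param K Rate matrix as from [build_rate_matrix()].
#' @param dt Time step in seconds (> 0).
#' @return Column-stochastic M x M matrix.
#' @export
transition_matrix <- function(K, dt) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K), dt > 0)
  if (any(!is.finite(K))) stop("non-finite entries in rate matrix")
  Tm <- as.matrix(Matrix::expm(K * dt))
  # clip tiny negative round-off and re-close columns
  Tm[Tm < 0 & Tm > -1e-12] <- 0
  cs <- colSums(Tm)
  if (any(abs(cs - 1) > 1e-8))
    stop("transition matrix columns deviate from 1 beyond tolerance")
  sweep(Tm, 2, cs, "/")
}

#' Equilibrium occupancy distribution of a rate matrix
#'
#' The normalized null vector p of K (K p = 0, p >= 0, sum 1). For
#' generators that are reducible at the given concentration (e.g. zero
#' ligand, where unbinding drains all liganded states) the stationary
#' distribution is still unique as long as there is a single closed
#' communicating class; multiple closed classes are reported as an
#' error listing the absorbing classes.
#'
#' @param K Rate matrix.
#' @return Probability vector of length M.
#' @export
equilibrium_distribution <- function(K) {
  M <- nrow(K)
  cls <- closed_classes(K)
  if (length(cls) > 1)
    stop("reducible chain with multiple absorbing classes: ",
         paste(vapply(cls, function(s) paste0("{", paste(s, collapse = ","),
                                              "}"), ""), collapse = " "))
  ns <- svd(K)$v[, M]
  p <- ns / sum(ns)
  p[abs(p) < 1e-14] <- 0
  if (any(p < -1e-10)) stop("null vector not a probability distribution")
  p <- pmax(p, 0)
  p / sum(p)
}

# resting occupancy used to initialize simulations and deterministic
# trajectories; a fully frozen generator (all rates zero) leaves every
# distribution stationary, in which case the ensemble is placed in the
# first state by convention.
resting_distribution <- function(K) {
  if (all(K == 0)) {
    p <- numeric(nrow(K)); p[1] <- 1
    return(p)
  }
  equilibrium_distribution(K)
}

# closed communicating classes of the support graph of K (column
# generator: edge j -> i present iff K[i,j] > 0)
closed_classes <- function(K, tol = 0) {
  M <- nrow(K)
  A <- (K > tol) & !diag(TRUE, M)   # A[i,j]: j -> i
  # reachability by repeated squaring of boolean matrix
  R <- A | diag(TRUE, M)
  for (k in seq_len(ceiling(log2(max(M, 2))))) {
    R <- (R %*% R) > 0
  }
  # state j's class is closed iff everything reachable from j reaches j
  classes <- list()
  seen <- rep(FALSE, M)
  for (j in seq_len(M)) {
    if (seen[j]) next
    reach <- which(R[, j])           # states reachable from j
    if (all(R[j, reach])) {          # each of them reaches back: closed class
      classes[[length(classes) + 1]] <- reach
      seen[reach] <- TRUE
    }
  }
  classes
}

#' Eigenvalues of the ensemble relaxation
#'
#' Real parts of the eigenvalues of K, sorted decreasingly. An
#' irreducible generator has exactly one zero mode (the equilibrium) and
#' all other real parts negative; `-1/alpha_i` for `i >= 2` are the
#' relaxation time constants used to normalize filter cut-off
#' frequencies (`f_cut / alpha_2`).
#'
#' @param K Rate matrix.
#' @return Numeric vector of sorted real parts (s^-1).
#' @export
relaxation_eigenvalues <- function(K) {
  if (any(!is.finite(K))) stop("non-finite entries in rate matrix")
  sort(Re(eigen(K, only.values = TRUE)$values), decreasing = TRUE)
}

#' Loop imbalance: clockwise over anticlockwise rate products
#'
#' For each declared cycle returns
#' `target * prod(denom) / prod(numer)`, i.e. the ratio of the two
#' directed rate products around the loop; 1 means microscopic
#' reversibility holds exactly.
#'
#' @param scheme A `kinetic_scheme` with declared loops.
#' @param rates Named rate values.
#' @return Numeric vector, one ratio per loop.
#' @export
loop_imbalance <- function(scheme, rates) {
  rates <- unlist(rates)
  if (!length(scheme$loops)) stop("scheme declares no loops")
  vapply(scheme$loops, function(lp) {
    refs <- c(lp$target, lp$numer, lp$denom)
    miss <- setdiff(refs, names(rates))
    if (length(miss))
      stop("loop references undeclared rate: ", paste(miss, collapse = ", "))
    unname(rates[lp$target] * prod(rates[lp$denom]) / prod(rates[lp$numer]))
  }, numeric(1))
}

#' Equilibrium constants of paired edges
#'
#' For every pair of states connected in both directions returns the
#' ratio forward/backward rate (forward = the direction written first
#' in the edge table). These ratios together with the forward rates are
#' the parameter set over which the Euclidean accuracy summary is
#' computed.
#'
#' @param scheme A `kinetic_scheme`.
#' @param rates Named rate values.
#' @return Named numeric vector of equilibrium constants `K_<pair>`.
#' @export
rate_ratios <- function(scheme, rates) {
  rates <- unlist(rates)
  e <- scheme$edges
  key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  out <- c()
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) != 2) next
    fwd <- idx[1]; bwd <- idx[2]
    nm <- paste0("K_", e$from[fwd], e$to[fwd])
    out[nm] <- unname(rates[e$param[fwd]] / rates[e$param[bwd]])
  }
  out
}

#' Read / write a scheme configuration file
#'
#' Declarative YAML listing states, edges, the conducting and
#' bound-ligand maps and optional loops; the on-disk format uses the
#' same 1-based state names as the constructor.
#'
#' @param path File path.
#' @return `read_scheme` returns a `kinetic_scheme`.
#' @export
read_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  kinetic_scheme(
    states = y$states,
    edges = tibble::as_tibble(do.call(rbind.data.frame, y$edges)),
    conducting = as.numeric(y$conducting),
    bound_ligands = as.integer(y$bound_ligands),
    loops = if (is.null(y$loops)) list() else y$loops,
    name = if (is.null(y$name)) "scheme" else y$name)
}

#' @param scheme A `kinetic_scheme` to serialize.
#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path) {
  y <- list(
    name = scheme$name,
    states = scheme$states,
    edges = purrr::transpose(as.list(scheme$edges)),
    conducting = scheme$conducting,
    bound_ligands = scheme$bound_ligands)
  if (length(scheme$loops)) y$loops <- scheme$loops
  yaml::write_yaml(y, path)
  invisible(path)
}
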