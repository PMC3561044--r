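#' Exact steady state of the traffic model on a small lattice
#'
#' Enumerates every configuration of the continuous-time Markov chain
#' (ribosome A-site positions with minimum gap `footprint`, each ribosome
#' in one of two internal states) and solves the stationary linear system.
#' Serves as an exact oracle for the Gillespie simulator; practical for
#' roughly L <= 8 at footprint 1.
#'
#' @param profile a `rate_profile`.
#' @param alpha initiation rate, s^-1.
#' @param config a `sim_config` (only `gamma`, `beta`, `footprint` used).
#' @param state_cap refuse to enumerate beyond this many states
#'   (default 2e5).
#' @return List with `J` (stationary termination flux, s^-1), `rho`
#'   (expected N/L), `entry_flux` (stationary initiation flux; equals `J`
#'   by flux conservation) and `n_states`.
#' @export
#' @examples
#' prof <- structure(list(gene_id = "one", codons = "AUG", k = 10),
#'                   class = "rate_profile")
#' cfg <- sim_config(beta = 35, footprint = 1)
#' exact_steady_state(prof, alpha = 1, cfg)$J  # 1 / (1/1 + 1/10 + 1/35)
exact_steady_state <- function(profile, alpha, config = sim_config(),
                               state_cap = 2e5) {
  stopifnot(inherits(profile, "rate_profile"), inherits(config, "sim_config"))
  if (alpha < 0) stop("alpha must be >= 0")
  k <- profile$k
  L <- length(k)
  ell <- config$footprint
  gamma <- config$gamma
  beta <- config$beta

  # all strictly increasing position vectors with gap >= ell
  pos_sets <- list(integer(0))
  grow <- function(prefix, min_next) {
    if (min_next > L) return(invisible(NULL))
    for (p in min_next:L) {
      pos_sets[[length(pos_sets) + 1L]] <<- c(prefix, p)
      grow(c(prefix, p), p + ell)
    }
  }
  grow(integer(0), 1L)

  n_states <- sum(vapply(pos_sets, function(ps) 2^length(ps), 1))
  if (n_states > state_cap)
    stop("state space has ", n_states, " states, exceeding cap ", state_cap)

  states <- vector("list", n_states)
  key_of <- function(pos, bound) paste(paste(pos, collapse = ","),
                                       paste(bound, collapse = ","), sep = "|")
  idx <- new.env(hash = TRUE, size = n_states)
  s <- 0L
  for (ps in pos_sets) {
    N <- length(ps)
    for (m in seq_len(max(1L, 2^N)) - 1L) {
      bound <- if (N == 0) integer(0) else as.integer(intToBits(m)[seq_len(N)])
      s <- s + 1L
      states[[s]] <- list(pos = ps, bound = bound)
      assign(key_of(ps, bound), s, envir = idx)
    }
  }

  from <- integer(0); to <- integer(0); rate <- numeric(0)
  add <- function(i, pos, bound, r) {
    j <- get(key_of(pos, bound), envir = idx)
    from[[length(from) + 1L]] <<- i
    to[[length(to) + 1L]] <<- j
    rate[[length(rate) + 1L]] <<- r
  }
  term_state <- logical(n_states)   # termination transition available
  entry_state <- logical(n_states)  # initiation transition available
  nrib <- integer(n_states)

  for (i in seq_len(n_states)) {
    st <- states[[i]]
    pos <- st$pos; bound <- st$bound; N <- length(pos)
    nrib[i] <- N
    if (N == 0 || pos[1] > ell) {
      entry_state[i] <- TRUE
      if (alpha > 0) add(i, c(1L, pos), c(0L, bound), alpha)
    }
    for (r in seq_len(N)) {
      if (bound[r] == 0L) {
        b2 <- bound; b2[r] <- 1L
        add(i, pos, b2, k[pos[r]])
      } else if (pos[r] == L) {
        term_state[i] <- TRUE
        add(i, pos[-r], bound[-r], beta)
      } else if (r == N || pos[r + 1] - pos[r] > ell) {
        p2 <- pos; p2[r] <- p2[r] + 1L
        b2 <- bound; b2[r] <- 0L
        add(i, p2, b2, gamma)
      }
    }
  }

  if (length(from) == 0) {  # alpha = 0 on an empty lattice: trivial
    return(list(J = 0, rho = 0, entry_flux = 0, n_states = n_states))
  }
  Q <- Matrix::sparseMatrix(i = from, j = to, x = rate,
                            dims = c(n_states, n_states))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  A <- Matrix::t(Q)
  A[1, ] <- 1  # replace one balance equation by the normalisation
  b <- c(1, rep(0, n_states - 1))
  pi_vec <- as.numeric(Matrix::solve(A, b))
  pi_vec[pi_vec < 0 & pi_vec > -1e-12] <- 0

  list(J = beta * sum(pi_vec[term_state]),
       rho = sum(pi_vec * nrib) / L,
       entry_flux = alpha * sum(pi_vec[entry_state]),
       n_states = n_states)
}
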