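#' Construct multi-state model parameters
#'
#' @param phi apparent survival per height state (per occasion interval).
#' @param alpha H x H movement matrix; each row a simplex over destination
#'   heights conditional on survival.
#' @param p recapture probability per height state.
#' @param heights optional height labels.
#' @return a [MultistateParams-class].
#' @examples
#' MultistateParams(phi = c(.8, .8, .85, .85),
#'                  alpha = matrix(.25, 4, 4),
#'                  p = c(.7, .7, .7, .7))
#' @export
MultistateParams <- function(phi, alpha, p, heights = character()) {
  new("MultistateParams", phi = as.numeric(phi), alpha = alpha,
      p = as.numeric(p), heights = as.character(heights))
}

#' Transition matrix of the multi-state model
#'
#' Builds the (H+1) x (H+1) state-transition matrix over live height
#' states 1..H and the absorbing dead state H+1.  For live h, h':
#' `psi[h, h'] = phi[h] * alpha[h, h']` (survive, then move) and
#' `psi[h, H+1] = 1 - phi[h]` (die); the dead row is (0, ..., 0, 1).
#' Every row sums to 1.
#'
#' @param params a [MultistateParams-class].
#' @return an (H+1) x (H+1) numeric matrix.
#' @examples
#' p <- MultistateParams(phi = c(.8, .9), alpha = diag(2), p = c(.5, .5))
#' transitionMatrix(p)
#' @export
transitionMatrix <- function(params) {
  validObject(params)
  H <- length(params@phi)
  psi <- matrix(0, H + 1L, H + 1L)
  psi[seq_len(H), seq_len(H)] <- params@phi * params@alpha
  psi[seq_len(H), H + 1L] <- 1 - params@phi
  psi[H + 1L, H + 1L] <- 1
  lab <- c(if (length(params@heights)) params@heights else
             paste0("h", seq_len(H)), "dead")
  dimnames(psi) <- list(from = lab, to = lab)
  psi
}

#' Observation matrix of the multi-state model
#'
#' Links true state (rows) to observed state (columns): a live frog at
#' height h is seen at h with probability `p[h]` and at no other height
#' (no height misclassification), otherwise not seen (column H+1).  Dead
#' individuals are unobservable: their row is (0, ..., 0, 1).
#'
#' @param params a [MultistateParams-class].
#' @return an (H+1) x (H+1) numeric matrix, columns 1..H = seen at that
#'   height, column H+1 = not seen.
#' @export
observationMatrix <- function(params) {
  validObject(params)
  H <- length(params@phi)
  omega <- matrix(0, H + 1L, H + 1L)
  diag(omega)[seq_len(H)] <- params@p
  omega[seq_len(H), H + 1L] <- 1 - params@p
  omega[H + 1L, H + 1L] <- 1
  lab <- if (length(params@heights)) params@heights else
    paste0("h", seq_len(H))
  dimnames(omega) <- list(state = c(lab, "dead"),
                          observation = c(lab, "not_seen"))
  omega
}
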