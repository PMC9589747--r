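# Shared fixtures and independent oracles.  Everything is generated in
# code; no stored data files.

# Brute-force likelihood of one capture history by enumeration over all
# latent state paths (live heights + dead), conditioned on y[f].
# Independent of the forward recursion: builds psi/omega from scratch and
# sums path products directly.
enumLoglik <- function(y, params, f = which(y > 0)[1L], last = length(y)) {
  phi <- survivalProb(params); alpha <- movementMatrix(params)
  p <- recaptureProb(params)
  H <- length(phi); S <- H + 1L
  psi <- rbind(cbind(phi * alpha, 1 - phi), c(rep(0, H), 1))
  steps <- seq(f + 1L, length.out = max(0L, last - f))
  if (!length(steps)) return(0)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), length(steps))))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    z <- c(y[f], paths[r, ])
    prob <- 1
    for (k in seq_along(steps)) {
      t <- steps[k]
      s <- z[k + 1L]
      prob <- prob * psi[z[k], s]
      obs <- y[t]
      prob <- prob * if (obs > 0) {
        if (s == obs) p[s] else 0
      } else {
        if (s <= H) 1 - p[s] else 1
      }
      if (prob == 0) break
    }
    total <- total + prob
  }
  log(total)
}

# Random valid multistate parameters (uses the current RNG stream).
randomParams <- function(H) {
  alpha <- matrix(rgamma(H * H, 1), H, H)
  alpha <- alpha / rowSums(alpha)
  MultistateParams(phi = runif(H, 0.05, 0.95), alpha = alpha,
                   p = runif(H, 0.05, 0.95))
}

# Minimal design: T biweekly occasions, one reference + one fire tree.
tinyDesign <- function(T = 5L, H = 3L) {
  occ <- as.Date("2021-03-05") + 14 * (0:(T - 1L))
  suppressWarnings(SamplingDesign(
    occasions = occ,
    trees = data.frame(
      tree_id = c("R1", "F1"), unit = c("U1", "U2"),
      treatment = c("reference", "fire_2021"),
      burn_date = c(as.Date(NA), occ[2L]),
      stringsAsFactors = FALSE),
    heights = paste0("h", seq_len(H))))
}

# Build a CaptureHistories object from a plain state matrix.
chFromMatrix <- function(y, design, last = NULL, removed = NULL) {
  n <- nrow(y)
  f <- apply(y, 1, function(r) which(r > 0)[1L])
  if (is.null(last)) last <- rep(ncol(y), n)
  if (is.null(removed)) removed <- rep(FALSE, n)
  newCaptureHistories(y = y, individual_id = sprintf("ind%03d", seq_len(n)),
                      tree_id = rep(studyTrees(design)$tree_id[1L], n),
                      f = f, last = last, removed = removed,
                      design = design)
}

# Deterministic detection set reproducing the field study's headline
# bookkeeping: 78 identified individuals, 199 recaptures (277 identified
# detections), 48 individuals recaptured at least once, 2 unidentified
# escapes, over the canonical 14-occasion, 12-tree design.
headlineDetections <- function(design = fireStudyDesign()) {
  trees <- studyTrees(design)$tree_id
  rows <- list()
  nDet <- c(rep(1L, 30), rep(5L, 41), rep(6L, 7))  # 30+205+42 = 277
  h <- 0L
  for (i in seq_len(78)) {
    f <- ((i - 1L) %% 9L) + 1L
    occ <- f + seq_len(nDet[i]) - 1L
    for (k in seq_along(occ)) {
      h <- h + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = sprintf("frog%02d", i), occasion = occ[k],
        tree_id = trees[((i - 1L) %% 12L) + 1L],
        height = ((h - 1L) %% 4L) + 1L, fate = "alive",
        mark_status = if (k == 1L) "new" else "recapture",
        stringsAsFactors = FALSE)
    }
  }
  for (k in 1:2)
    rows[[length(rows) + 1L]] <- data.frame(
      individual_id = "UNIDENTIFIED", occasion = 6L + k,
      tree_id = trees[k], height = 2L, fate = "alive",
      mark_status = "new", stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

quietFit <- function(expr) suppressWarnings(suppressMessages(expr))
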