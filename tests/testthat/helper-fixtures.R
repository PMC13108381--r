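## Shared fixtures, built in code at test time.

## a CellCounts whose per-cell genes-detected metric is exactly `detected`
makeQCMatrix <- function(detected, nGenes = 15, readsPerGene = 50) {
  counts <- sapply(seq_along(detected), function(i) {
    v <- numeric(nGenes)
    v[seq_len(detected[i])] <- readsPerGene
    v
  })
  rownames(counts) <- paste0("g", seq_len(nGenes))
  CellCounts(counts)
}

## straight horizontal tube truth
tubeTruth <- function(width = 4, length = 100, frame = 200,
                      pixelSize = 0.5, ...) {
  VesselGroundTruth(
    data.frame(x0 = (frame - length) / 2, y0 = frame / 2,
               x1 = (frame + length) / 2, y1 = frame / 2, width = width),
    imageSize = c(frame, frame), pixelSize = pixelSize, ...)
}

## three segments meeting at a single hub (one true branch point)
yNetworkTruth <- function(pixelSize = 0.5, ...) {
  segs <- data.frame(x0 = c(20, 100, 100), y0 = c(100, 100, 100),
                     x1 = c(100, 170, 170), y1 = c(100, 40, 160),
                     width = c(5, 4, 4))
  VesselGroundTruth(segs, imageSize = c(200, 200),
                    pixelSize = pixelSize, ...)
}

## brute-force anisotropic distance transform (independent oracle)
bruteDT3 <- function(mask, vx) {
  dims <- dim(mask)
  src <- which(mask, arr.ind = TRUE)
  out <- array(Inf, dims)
  if (!nrow(src)) return(out)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      d2 <- ((i - src[, 1]) * vx[1])^2 + ((j - src[, 2]) * vx[2])^2 +
        ((k - src[, 3]) * vx[3])^2
      out[i, j, k] <- sqrt(min(d2))
    }
  out
}

## simple 6-subclass splicing truth: half high-inclusion, half low
neuronEndoPsi <- function(nEvents = 6, seed = 2) {
  psi <- matrix(rep(c(0.9, 0.92, 0.88, 0.1, 0.12, 0.08), each = nEvents),
                nEvents, 6,
                dimnames = list(paste0("ev", seq_len(nEvents)),
                                c(paste0("neuron", 1:3),
                                  paste0("endo", 1:3))))
  set.seed(seed)
  pmin(pmax(psi + stats::runif(length(psi), -0.03, 0.03), 0), 1)
}
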