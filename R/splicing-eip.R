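## Exon-inclusion-proportion quantification from splice-junction reads,
## subclass aggregation, variance partitioning, PCA and exon coding
## arithmetic.

#' Read STAR SJ.out.tab junction counts against an exon-event annotation
#'
#' Parses one or more files in the STAR `SJ.out.tab` column layout
#' (chrom, intron start, intron end, strand, motif, annotated, unique
#' reads, multi-mapping reads, max overhang; coordinates 1-based on the
#' first/last intron base) and assigns unique-read counts to the
#' inclusion/exclusion slots of each annotated exon event by exact
#' coordinate match. Multi-mapping reads are ignored. Junctions matching
#' no annotation are retained in a side table
#' (`metadata(result)$unmatched`).
#'
#' The annotation is a data.frame with one row per exon event:
#' `gene`, `event`, `variantGroup` (`NA` for plain cassette exons),
#' `chrom`, `strand` (`"+"`/`"-"`/`"*"`), the upstream and downstream
#' inclusion junction intron bounds `inc1Start`, `inc1End`, `inc2Start`,
#' `inc2End` (`NA` allowed for the second junction, e.g. splice-site
#' variants identified by a single unique junction) and the exclusion
#' junction bounds `excStart`, `excEnd`.
#'
#' @param paths character vector of file paths; names are used as cell
#'   identifiers (one file per cell). Alternatively a single file whose
#'   first column is a cell identifier followed by the nine SJ columns.
#' @param annotation exon-event annotation data.frame (see Details).
#' @param ignoreStrand if `TRUE`, junctions match regardless of strand.
#' @return a [JunctionCounts] object (events x cells).
#' @export
readSJTab <- function(paths, annotation, ignoreStrand = FALSE) {
  checkAnnotation(annotation)
  tabs <- list()
  if (length(paths) == 1 && is.null(names(paths))) {
    raw <- readLines(paths)
    raw <- raw[nzchar(raw)]
    fields <- strsplit(raw, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (length(nf) && all(nf == 10)) {
      df <- parseSJLines(raw, paths, withCell = TRUE)
      tabs <- split(df, df$cell)
    } else {
      tabs <- list(cell1 = parseSJLines(raw, paths, withCell = FALSE))
    }
  } else {
    if (is.null(names(paths)))
      names(paths) <- paste0("cell", seq_along(paths))
    tabs <- lapply(paths, function(p) {
      raw <- readLines(p)
      parseSJLines(raw[nzchar(raw)], p, withCell = FALSE)
    })
  }
  cells <- names(tabs)
  nev <- nrow(annotation)
  I <- matrix(0, nev, length(cells))
  E <- matrix(0, nev, length(cells))
  unmatched <- list()
  strandCode <- c("+" = 1L, "-" = 2L, "*" = 0L)[annotation$strand]
  for (j in seq_along(cells)) {
    sj <- tabs[[j]]
    key <- paste(sj$chrom, sj$start, sj$end)
    hit <- rep(FALSE, nrow(sj))
    for (i in seq_len(nev)) {
      a <- annotation[i, ]
      strandOK <- if (ignoreStrand || is.na(strandCode[i]) ||
                      strandCode[i] == 0L) rep(TRUE, nrow(sj))
                  else sj$strand == strandCode[i] | sj$strand == 0L
      incKeys <- c(paste(a$chrom, a$inc1Start, a$inc1End),
                   if (!is.na(a$inc2Start))
                     paste(a$chrom, a$inc2Start, a$inc2End))
      mInc <- key %in% incKeys & strandOK
      mExc <- key == paste(a$chrom, a$excStart, a$excEnd) & strandOK
      I[i, j] <- sum(sj$unique[mInc])
      E[i, j] <- sum(sj$unique[mExc])
      hit <- hit | mInc | mExc
    }
    if (any(!hit))
      unmatched[[cells[j]]] <- cbind(cell = cells[j],
                                     sj[!hit, , drop = FALSE])
  }
  colnames(I) <- colnames(E) <- cells
  jc <- JunctionCounts(I, E, gene = annotation$gene,
                       event = annotation$event,
                       variantGroup = annotation$variantGroup)
  metadata(jc)$unmatched <-
    if (length(unmatched)) do.call(rbind, unmatched)
    else data.frame()
  jc
}

parseSJLines <- function(raw, path, withCell = FALSE) {
  n <- if (withCell) 10L else 9L
  if (!length(raw)) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = numeric(0),
                      unique = numeric(0))
    if (withCell) out$cell <- character(0)
    return(out)
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != n)
  if (length(bad))
    stop(sprintf("malformed SJ line %d in %s (expected %d fields)",
                 bad[1], path, n))
  m <- do.call(rbind, fields)
  off <- if (withCell) 1L else 0L
  num <- suppressWarnings(apply(m[, off + c(2:5, 7), drop = FALSE], 2,
                                as.numeric))
  num <- matrix(num, nrow = nrow(m))
  if (anyNA(num))
    stop(sprintf("malformed SJ line %d in %s (non-numeric field)",
                 which(rowSums(is.na(num)) > 0)[1], path))
  out <- data.frame(chrom = m[, off + 1L], start = num[, 1],
                    end = num[, 2], strand = num[, 3],
                    unique = num[, 5])
  if (withCell) out$cell <- m[, 1L]
  out
}

checkAnnotation <- function(annotation) {
  need <- c("gene", "event", "variantGroup", "chrom", "strand",
            "inc1Start", "inc1End", "inc2Start", "inc2End",
            "excStart", "excEnd")
  miss <- setdiff(need, names(annotation))
  if (length(miss))
    stop("annotation is missing columns: ", paste(miss, collapse = ", "))
  ok <- with(annotation, inc1Start < inc1End &
               (is.na(inc2Start) | inc2Start < inc2End) &
               excStart < excEnd)
  if (!all(ok)) stop("annotation junction coordinates must be ordered")
  invisible(TRUE)
}

#' Exon inclusion proportion from junction read counts
#'
#' EIP = I / (I + 2E), where I counts reads over the two exon-flanking
#' inclusion junctions (an including transcript contributes two such
#' junctions) and E counts reads over the single exon-skipping junction.
#' The doubled E balances the two-to-one junction multiplicity, making
#' the proportion an unbiased transcript-level inclusion estimate.
#'
#' @param I,E non-negative inclusion / exclusion read counts
#'   (vectorized).
#' @return EIP in \eqn{[0,1]}; `NA` where `I = E = 0`.
#' @examples
#' computeEIP(10, 5)  # 0.5
#' @export
computeEIP <- function(I, E) {
  if (any(I < 0, na.rm = TRUE) || any(E < 0, na.rm = TRUE))
    stop("junction read counts must be non-negative")
  out <- I / (I + 2 * E)
  out[I == 0 & E == 0] <- NA_real_
  out
}

#' EIP for mutually exclusive junction variants of one exon
#'
#' For an exon with two alternative splice-site variants a and b sharing
#' one exclusion junction, EIP_a = I_a / (I_a + I_b + E) and
#' symmetrically for b, so the variant EIPs can never sum above one.
#'
#' @param Ia,Ib unique-junction inclusion reads of variants a and b.
#' @param E shared exclusion junction reads.
#' @return two-column matrix `(a, b)`; both `NA` where all counts are 0.
#' @examples
#' computeVariantEIP(6, 2, 1)  # 6/9, 2/9
#' @export
computeVariantEIP <- function(Ia, Ib, E) {
  if (any(c(Ia, Ib, E) < 0, na.rm = TRUE))
    stop("junction read counts must be non-negative")
  tot <- Ia + Ib + E
  a <- Ia / tot
  b <- Ib / tot
  a[tot == 0] <- NA_real_
  b[tot == 0] <- NA_real_
  cbind(a = a, b = b)
}

#' Detection gate for (cell, event) pairs
#'
#' A pair is analyzable when either its inclusion or its exclusion
#' junction reads exceed 1 log2(CPM+1), with CPM computed against the
#' cell's total mapped reads. The comparison is strict, so a read level
#' landing exactly on 1 fails.
#'
#' @param jc a [JunctionCounts] object.
#' @param total per-cell total mapped reads (defaults to
#'   `cellTotals(jc)`).
#' @param threshold gate on the log2(CPM+1) scale (default 1).
#' @return logical events x cells matrix.
#' @export
detectionGate <- function(jc, total = NULL, threshold = 1) {
  if (is.null(total)) total <- cellTotals(jc)
  if (anyNA(total) || any(total <= 0))
    stop("positive per-cell totals are required for the detection gate")
  lI <- logNormalize(sweep(assay(jc, "I"), 2, total, "/") * 1e6)
  lE <- logNormalize(sweep(assay(jc, "E"), 2, total, "/") * 1e6)
  lI > threshold | lE > threshold
}

#' Per-cell EIP matrix
#'
#' Computes per-cell EIPs for every annotated event, using the plain
#' cassette formula for ordinary events and the mutually exclusive
#' formula within variant groups. Pairs failing the detection gate (if
#' supplied) are set to missing.
#'
#' @param jc a [JunctionCounts] object.
#' @param gate optional logical events x cells matrix from
#'   [detectionGate()].
#' @return an [EIPMatrix] at cell level; the `reads` slot holds the
#'   denominator mass supporting each value.
#' @export
cellEIP <- function(jc, gate = NULL) {
  I <- assay(jc, "I"); E <- assay(jc, "E")
  vg <- rowData(jc)$variantGroup
  eip <- computeEIP(I, E)
  reads <- I + 2 * E
  for (g in unique(vg[!is.na(vg)])) {
    idx <- which(vg == g)
    if (length(idx) != 2) next
    ve <- computeVariantEIP(I[idx[1], ], I[idx[2], ], E[idx[1], ])
    eip[idx[1], ] <- ve[, "a"]
    eip[idx[2], ] <- ve[, "b"]
    tot <- I[idx[1], ] + I[idx[2], ] + E[idx[1], ]
    reads[idx[1], ] <- reads[idx[2], ] <- tot
  }
  if (!is.null(gate)) eip[!gate] <- NA_real_
  new("EIPMatrix", eip = eip, reads = reads,
      nCells = matrix(numeric(0), 0, 0), level = "cell")
}

#' Aggregate per-cell EIPs into subclass summaries
#'
#' Two aggregation modes are offered. `"mean"` (default) averages the
#' per-cell EIPs of gated cells, matching a per-cell analysis; `"pooled"`
#' sums gated inclusion and exclusion reads within the subclass and
#' applies the EIP formula once, which weights cells by depth and is the
#' estimator whose standard error follows directly from read counts
#' (see [pooledEIPSE()]). A subclass is only emitted when it contains
#' more than `minCells` cells in total.
#'
#' @param jc a [JunctionCounts] object with subclass labels.
#' @param minCells exclusive minimum subclass size (default 100).
#' @param mode `"mean"` or `"pooled"`.
#' @param gate optional logical gate matrix from [detectionGate()].
#' @param labels per-cell subclass labels (defaults to those carried by
#'   `jc`).
#' @return an [EIPMatrix] at subclass level; `nCells` counts the cells
#'   contributing to each entry.
#' @export
aggregateBySubclass <- function(jc, minCells = 100,
                                mode = c("mean", "pooled"),
                                gate = NULL, labels = NULL) {
  mode <- match.arg(mode)
  if (is.null(labels)) labels <- subclassLabels(jc)
  if (length(labels) != ncol(jc))
    stop("'labels' must have one entry per cell")
  sizes <- table(labels)
  subs <- names(sizes)[sizes > minCells]
  if (!length(subs))
    warning("no subclass exceeds the minimum cell count")
  I <- assay(jc, "I"); E <- assay(jc, "E")
  perCell <- eipValues(cellEIP(jc, gate = gate))
  nev <- nrow(jc)
  eip <- reads <- ncells <- matrix(NA_real_, nev, length(subs),
                                   dimnames = list(rownames(jc), subs))
  for (s in subs) {
    cols <- which(labels == s)
    ok <- !is.na(perCell[, cols, drop = FALSE])
    ncells[, s] <- rowSums(ok)
    if (mode == "mean") {
      eip[, s] <- rowMeans(perCell[, cols, drop = FALSE], na.rm = TRUE)
      reads[, s] <- rowSums((assayMass(I, E, jc))[, cols, drop = FALSE] * ok)
    } else {
      Ig <- I[, cols, drop = FALSE]; Eg <- E[, cols, drop = FALSE]
      Ig[!ok] <- 0; Eg[!ok] <- 0
      sI <- rowSums(Ig); sE <- rowSums(Eg)
      eip[, s] <- computeEIP(sI, sE)
      reads[, s] <- sI + sE
    }
  }
  eip[is.nan(eip)] <- NA_real_
  new("EIPMatrix", eip = eip, reads = reads, nCells = ncells,
      level = "subclass")
}

assayMass <- function(I, E, jc) I + 2 * E

#' Delta-method standard error of the pooled EIP estimator
#'
#' Under the two-junctions-per-including-transcript read model, each of
#' the N = I + E junction reads is an inclusion read with probability
#' p = 2 psi / (1 + psi). The pooled EIP equals p-hat / (2 - p-hat);
#' propagating the binomial error of p-hat gives
#' SE = 2 / (2 - p-hat)^2 * sqrt(p-hat (1 - p-hat) / N).
#'
#' @param I,E pooled inclusion / exclusion read counts.
#' @return standard error of the pooled EIP (0 when p-hat is 0 or 1).
#' @export
pooledEIPSE <- function(I, E) {
  N <- I + E
  p <- ifelse(N > 0, I / N, NA_real_)
  2 / (2 - p)^2 * sqrt(p * (1 - p) / N)
}

#' Splicing variation across subclasses
#'
#' Per-event population variance (standard deviation squared, divisor
#' n) of subclass EIPs, per-gene summed variance, and each gene's
#' fraction of the summed variance across the gene family. Events with
#' fewer than two observed subclasses are skipped with a warning;
#' missing entries are excluded per event (complete-case).
#'
#' @param x an [EIPMatrix] at subclass level, or a plain events x
#'   subclasses matrix.
#' @param genes per-event gene assignment (defaults to the prefix of
#'   the rowname before the first `.`).
#' @return list with `perEvent` (data.frame: gene, event, variance, n),
#'   `perGene` (named vector of summed variances) and `familyFraction`
#'   (named vector summing to 1).
#' @export
splicingVariation <- function(x, genes = NULL) {
  m <- if (is(x, "EIPMatrix")) eipValues(x) else as.matrix(x)
  if (is.null(genes))
    genes <- sub("\\..*$", "", rownames(m))
  nobs <- rowSums(!is.na(m))
  if (any(nobs < 2)) {
    warning(sprintf("skipping %d event(s) observed in <2 subclasses",
                    sum(nobs < 2)))
  }
  keep <- nobs >= 2
  popVar <- function(v) { v <- v[!is.na(v)]; mean((v - mean(v))^2) }
  variance <- apply(m[keep, , drop = FALSE], 1, popVar)
  perEvent <- data.frame(gene = genes[keep],
                         event = rownames(m)[keep],
                         variance = variance, n = nobs[keep],
                         row.names = NULL)
  perGene <- tapply(perEvent$variance, perEvent$gene, sum)
  perGene <- perGene[!is.na(perGene)]
  list(perEvent = perEvent, perGene = c(perGene),
       familyFraction = c(perGene / sum(perGene)))
}

#' Centered, unscaled PCA of subclass splicing profiles
#'
#' Column-centered principal component analysis (no variance scaling)
#' of a complete subclasses x events EIP matrix, as produced after
#' expression gating. Missing entries are an error: gate or complete
#' the matrix first. Component signs are fixed by forcing the
#' largest-magnitude loading of each component positive, so outputs are
#' reproducible.
#'
#' @param x subclasses x events numeric matrix (observations in rows),
#'   or a subclass-level [EIPMatrix] (transposed internally).
#' @return list with `scores` (subclasses x components), `loadings`
#'   (events x components), `explained` (variance ratios, non-increasing),
#'   `center` (column means) and `degenerate` (`TRUE` when total
#'   variance is zero).
#' @export
pcaEmbed <- function(x) {
  m <- if (is(x, "EIPMatrix")) t(eipValues(x)) else as.matrix(x)
  if (anyNA(m))
    stop("EIP matrix contains missing values; apply the detection and ",
         "expression gates (or restrict to complete events) before PCA")
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  tot <- sum(p$sdev^2)
  degenerate <- tot <= .Machine$double.eps
  explained <- if (degenerate) rep(0, length(p$sdev)) else p$sdev^2 / tot
  for (k in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, k]))
    if (p$rotation[i, k] < 0) {
      p$rotation[, k] <- -p$rotation[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  if (degenerate)
    warning("zero total variance: explained-variance ratios are degenerate")
  list(scores = p$x, loadings = p$rotation, explained = explained,
       center = p$center, degenerate = degenerate)
}

#' Coding impact of an alternatively spliced exon
#'
#' Length arithmetic for cassette exons: an exon whose length is
#' divisible by three inserts a fixed run of amino acids without
#' shifting the downstream reading frame -- the property shared by the
#' four major alternatively spliced Adgrl2 exons.
#'
#' @param sequence exon nucleotide sequence(s): character vector or
#'   [Biostrings::DNAStringSet]. A/C/G/T only.
#' @return data.frame with `length` (nt), `divisibleBy3` and
#'   `aminoAcids` (length/3 when in-frame, otherwise `NA`).
#' @examples
#' exonCodingImpact("ATGATG")  # 6 nt, in frame, 2 aa
#' @export
exonCodingImpact <- function(sequence) {
  if (is(sequence, "XStringSet")) {
    nms <- names(sequence)
    sequence <- as.character(sequence)
    names(sequence) <- nms
  }
  if (any(!nzchar(sequence))) stop("exon sequence must be non-empty")
  if (any(grepl("[^ACGTacgt]", sequence)))
    stop("exon sequence must contain only A/C/G/T")
  len <- nchar(sequence)
  div3 <- len %% 3 == 0
  data.frame(length = len, divisibleBy3 = div3,
             aminoAcids = ifelse(div3, len %/% 3, NA_integer_),
             row.names = names(sequence))
}

#' Packaged latrophilin exon sequences
#'
#' The alternatively spliced exon sequences of the mouse latrophilin
#' family (Adgrl1/2/3) shipped with the package, as a
#' [Biostrings::DNAStringSet] named `<gene>_exon<label>`. Includes the
#' four major Adgrl2 cassette exons (9, 14, 23, 28) and representative
#' splice-site variant pairs.
#'
#' @return a [Biostrings::DNAStringSet].
#' @export
#' @importFrom Biostrings readDNAStringSet
adgrlExonSequences <- function() {
  readDNAStringSet(system.file("extdata", "adgrl_exons.fa",
                               package = "SpliceVasc"))
}
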