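#' Shared coding somatic variants between paired tumors
#'
#' Intersection keyed on (gene, protein change): distinct protein changes in
#' the same gene do not match, and entries without a protein change never
#' match (a gene symbol alone does not identify a variant).
#'
#' @param setA,setB data.frames with columns `gene`, `protein_change`
#'   (e.g. from [parse_variant_list()]).
#' @return data.frame of shared variants (`gene`, `protein_change`).
#' @export
shared_coding <- function(setA, setB) {
  keyed <- function(s) {
    ok <- !is.na(s$protein_change) & nzchar(s$protein_change)
    paste(toupper(s$gene[ok]), s$protein_change[ok])
  }
  ka <- keyed(setA); kb <- keyed(setB)
  shared_keys <- unique(intersect(ka, kb))
  ok <- !is.na(setA$protein_change) & nzchar(setA$protein_change)
  sub <- setA[ok, , drop = FALSE]
  out <- sub[paste(toupper(sub$gene), sub$protein_change) %in% shared_keys,
             c("gene", "protein_change"), drop = FALSE]
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Count shared noncoding somatic variants
#'
#' Size of the intersection of two noncoding variant sets keyed on exact
#' (chrom, pos, ref, alt) — whole-genome calls from the same patient share
#' coordinates, so no fuzzy matching is applied.
#'
#' @param setA,setB data.frames with columns `chrom`, `pos`, `ref`, `alt`.
#' @return integer count.
#' @export
count_shared_noncoding <- function(setA, setB) {
  key <- function(s) unique(paste(s$chrom, s$pos, s$ref, s$alt))
  length(intersect(key(setA), key(setB)))
}

#' Classify a copy-number segment value
#'
#' Log2-ratio scale: `>= 0.5` gain, `<= -0.5` loss, `[0.1, 0.5)` low-level
#' gain, `(-0.5, -0.1]` low-level loss, `(-0.1, 0.1)` neutral.
#'
#' @param value numeric vector of segment values.
#' @return character vector in
#'   `{gain, loss, low_gain, low_loss, neutral}`.
#' @export
classify_cnv_value <- function(value) {
  stopifnot(all(is.finite(value)))
  ifelse(value >= 0.5, "gain",
  ifelse(value <= -0.5, "loss",
  ifelse(value >= 0.1, "low_gain",
  ifelse(value <= -0.1, "low_loss", "neutral"))))
}

bin_profile <- function(segs, breaks_by_chrom, bin_size) {
  # per-bin value from the covering segment; 0 where uncovered
  out <- numeric(0)
  for (chrom in names(breaks_by_chrom)) {
    starts <- breaks_by_chrom[[chrom]]
    vals <- numeric(length(starts))
    s <- segs[segs$chrom == chrom, , drop = FALSE]
    if (nrow(s)) {
      mids <- starts + bin_size / 2
      for (i in seq_along(mids)) {
        hit <- which(s$start <= mids[i] & s$end >= mids[i])
        if (length(hit)) vals[i] <- s$value[hit[1]]
      }
    }
    out <- c(out, vals)
  }
  out
}

#' Genome-wide copy-number profile similarity
#'
#' Bins the genome span covered by either profile at `bin_size`, assigns each
#' bin the value of the covering segment (0 where uncovered, i.e. neutral),
#' and returns the Pearson correlation of the two bin vectors. When either
#' vector is constant the correlation is undefined; similarity is then 1 if
#' the vectors are identical, 0 otherwise.
#'
#' @param segsA,segsB `CnvSegments`-style data.frames for one sample each
#'   (columns `chrom`, `start`, `end`, `value`).
#' @param bin_size bin width in bp (default 1 Mb).
#' @return similarity in \[-1, 1\].
#' @export
cnv_profile_similarity <- function(segsA, segsB, bin_size = bwt_config()$cnv_bin_size) {
  if (nrow(segsA) == 0L || nrow(segsB) == 0L) {
    stop_validation("empty copy-number profile")
  }
  chroms <- union(unique(segsA$chrom), unique(segsB$chrom))
  breaks <- lapply(setNames(chroms, chroms), function(ch) {
    lo <- min(c(segsA$start[segsA$chrom == ch], segsB$start[segsB$chrom == ch]))
    hi <- max(c(segsA$end[segsA$chrom == ch], segsB$end[segsB$chrom == ch]))
    seq(from = floor((lo - 1) / bin_size) * bin_size + 1, to = hi, by = bin_size)
  })
  a <- bin_profile(segsA, breaks, bin_size)
  b <- bin_profile(segsB, breaks, bin_size)
  if (sd(a) == 0 || sd(b) == 0) {
    return(if (isTRUE(all.equal(a, b))) 1 else 0)
  }
  cor(a, b)
}

find_11p_cnloh <- function(segs, region) {
  s <- segs[segs$chrom == region$chrom & as.logical(segs$cnloh) &
              segs$start <= region$end & segs$end >= region$start, ,
            drop = FALSE]
  if (nrow(s) == 0L) return(NULL)
  s[order(s$start), , drop = FALSE][1, , drop = FALSE]
}

#' Compare 11p cnLOH breakpoints between paired tumors
#'
#' Locates the copy-neutral LOH segment overlapping the 11p15.5 imprinted
#' region in each tumor and reports whether both the start and the end
#' breakpoints agree within `tol_bp`.
#'
#' @param segsA,segsB per-sample segment data.frames (with `cnloh`).
#' @param tol_bp breakpoint tolerance in bp (default 10 kb).
#' @param config a [bwt_config()] list (11p15.5 window).
#' @return `TRUE`/`FALSE`, or `NA` when either tumor lacks an overlapping
#'   cnLOH segment.
#' @export
compare_11p_breakpoints <- function(segsA, segsB,
                                    tol_bp = bwt_config()$breakpoint_tol_bp,
                                    config = bwt_config()) {
  region <- config$region_11p15
  a <- find_11p_cnloh(segsA, region)
  b <- find_11p_cnloh(segsB, region)
  if (is.null(a) || is.null(b)) return(NA)
  abs(a$start - b$start) <= tol_bp && abs(a$end - b$end) <= tol_bp
}

#' Classify the developmental origin of a synchronous tumor pair
#'
#' Many shared noncoding variants together with a near-identical genome-wide
#' copy-number profile are atypical for true bilateral disease and suggest
#' multifocal tumors of one kidney; any sharing at all places the pair's
#' divergence after a common initiated clone (early embryonic); no sharing is
#' consistent with independent origins (e.g. a germline first hit).
#'
#' @param n_shared_noncoding integer shared noncoding count.
#' @param shared_coding_n number of shared coding variants (default 0).
#' @param cnv_similarity profile similarity in \[-1, 1\], or NA when no
#'   profile comparison is available (NA fails the atypical test).
#' @param config a [bwt_config()] list (`atypical_shared_noncoding`,
#'   `atypical_cnv_similarity`).
#' @return one of `"independent"`, `"shared_early_clone"`,
#'   `"suspected_same_kidney_multifocal"`.
#' @export
classify_pair_origin <- function(n_shared_noncoding, shared_coding_n = 0L,
                                 cnv_similarity = NA_real_,
                                 config = bwt_config()) {
  if (n_shared_noncoding >= config$atypical_shared_noncoding &&
      !is.na(cnv_similarity) &&
      cnv_similarity >= config$atypical_cnv_similarity) {
    return("suspected_same_kidney_multifocal")
  }
  if (n_shared_noncoding >= 1L || shared_coding_n >= 1L) {
    return("shared_early_clone")
  }
  "independent"
}

#' Full concordance summary for one synchronous pair
#'
#' @param patient_id patient identifier.
#' @param codingA,codingB coding variant data.frames (`gene`,
#'   `protein_change`).
#' @param noncodingA,noncodingB noncoding variant data.frames (`chrom`,
#'   `pos`, `ref`, `alt`).
#' @param icrA,icrB imprinting status strings for the two tumors.
#' @param segsA,segsB optional per-tumor CNV segment data.frames.
#' @param config a [bwt_config()] list.
#' @return list of class `PairConcordance` with `patient_id`,
#'   `shared_coding`, `n_shared_noncoding`, `icr_concordant`,
#'   `cnv_similarity`, `breakpoints_11p_identical`, `origin_call`.
#' @export
pair_concordance <- function(patient_id, codingA, codingB, noncodingA,
                             noncodingB, icrA, icrB, segsA = NULL,
                             segsB = NULL, config = bwt_config()) {
  sc <- shared_coding(codingA, codingB)
  nsn <- count_shared_noncoding(noncodingA, noncodingB)
  sim <- if (!is.null(segsA) && !is.null(segsB) && nrow(segsA) && nrow(segsB)) {
    cnv_profile_similarity(segsA, segsB, config$cnv_bin_size)
  } else NA_real_
  bp <- if (!is.null(segsA) && !is.null(segsB)) {
    compare_11p_breakpoints(segsA, segsB, config$breakpoint_tol_bp, config)
  } else NA
  structure(list(
    patient_id = patient_id,
    shared_coding = sc,
    n_shared_noncoding = nsn,
    icr_concordant = identical(icrA, icrB),
    cnv_similarity = sim,
    breakpoints_11p_identical = bp,
    origin_call = classify_pair_origin(nsn, nrow(sc), sim, config)
  ), class = "PairConcordance")
}
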