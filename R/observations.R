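#' Observation sets
#'
#' Container for the processed per-cell measurements used for copy number
#' calling: read depths `R` (N cells x L segments, proportional to total copy
#' number times a cell-specific scaling factor), B-allele frequencies `B`
#' (proportion of reads from the second haplotype), optional haplotype read
#' counts `A` (N x L x 2), and per-cell/segment variances `sigmaR` and
#' `sigmaB` for the Gaussian observation model.
#'
#' When `B` is absent it is derived from `A` as `A2 / (A1 + A2)`; segments
#' with no allele reads get `B = 0.5` and a maximal BAF variance so they
#' carry no allelic signal.
#'
#' @param R numeric N x L matrix of nonnegative read depths.
#' @param segments an [segment_table()] with L rows.
#' @param B optional numeric N x L matrix in `[0, 1]`.
#' @param A optional N x L x 2 array of nonnegative haplotype read counts.
#' @param sigmaR,sigmaB optional strictly positive N x L variance matrices;
#'   derived by [fallback_variances()] when missing.
#' @param scaling optional length-N positive per-cell scaling factors
#'   (defaults to 1; typically estimated by [call_naive()]).
#' @param cell_ids optional character vector of N cell barcodes.
#' @return Object of class `evocn_obs`.
#' @export
observation_set <- function(R, segments, B = NULL, A = NULL,
                            sigmaR = NULL, sigmaB = NULL,
                            scaling = NULL, cell_ids = NULL) {
  R <- as.matrix(R)
  N <- nrow(R); L <- ncol(R)
  if (L != n_segments(segments))
    stopf("observations: R has %d columns but segment table has %d rows",
          L, n_segments(segments))
  if (any(R < 0)) stopf("observations: negative read depth in R")
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%04d", seq_len(N))
  if (length(cell_ids) != N) stopf("observations: cell_ids length != N")

  if (!is.null(A)) {
    if (!identical(dim(A)[1:2], dim(R)) || dim(A)[3] != 2L)
      stopf("observations: A must be an N x L x 2 array matching R")
    if (any(A < 0)) stopf("observations: negative counts in A")
  }
  if (is.null(B)) {
    if (is.null(A)) stopf("observations: need B or A")
    B <- baf_from_counts(A)
  } else {
    B <- as.matrix(B)
    if (!identical(dim(B), dim(R)))
      stopf("observations: B dimensions do not match R")
    if (any(B < 0 | B > 1)) stopf("observations: B outside [0, 1]")
  }
  check_var <- function(S, nm) {
    if (is.null(S)) return(NULL)
    S <- as.matrix(S)
    if (!identical(dim(S), dim(R)))
      stopf("observations: %s dimensions do not match R", nm)
    if (any(S <= 0)) stopf("observations: %s must be strictly positive", nm)
    S
  }
  sigmaR <- check_var(sigmaR, "sigmaR")
  sigmaB <- check_var(sigmaB, "sigmaB")
  if (is.null(scaling)) scaling <- rep(1, N)
  if (length(scaling) != N || any(scaling <= 0))
    stopf("observations: scaling must be N positive values")

  obs <- structure(list(R = R, B = B, A = A, sigmaR = sigmaR, sigmaB = sigmaB,
                        scaling = as.numeric(scaling),
                        cell_ids = as.character(cell_ids),
                        segments = segments),
                   class = "evocn_obs")
  if (is.null(obs$sigmaR) || is.null(obs$sigmaB))
    obs <- fallback_variances(obs)
  obs
}

#' Derive BAFs from haplotype read counts
#'
#' `B = A2 / (A1 + A2)`; zero-total entries are neutral at 0.5.
#' @param A N x L x 2 array of haplotype read counts.
#' @return N x L matrix in `[0, 1]`.
#' @export
baf_from_counts <- function(A) {
  a1 <- matrix(A[, , 1], dim(A)[1], dim(A)[2])   # keep dims at N = 1
  a2 <- matrix(A[, , 2], dim(A)[1], dim(A)[2])
  tot <- a1 + a2
  B <- a2 / ifelse(tot > 0, tot, 1)
  B[tot == 0] <- 0.5
  B
}

#' Fallback variance estimates
#'
#' Stand-in moment-based variance estimates for runs where upstream
#' (pipeline-specific) variance estimation is unavailable. Read-depth
#' variance is a constant dispersion times the cell's mean depth; BAF
#' variance is the binomial variance of a balanced allele ratio given the
#' observed allele coverage. Both are floored at `v_floor` so likelihoods
#' stay finite.
#'
#' @param obs an [observation_set()].
#' @param snp_counts optional N x L matrix of total allele read counts used
#'   for the BAF variance when `A` is absent.
#' @param dispersion read-depth dispersion constant (default 0.05).
#' @param v_floor variance floor (default 1e-6).
#' @return `obs` with `sigmaR`/`sigmaB` filled in where missing.
#' @export
fallback_variances <- function(obs, snp_counts = NULL, dispersion = 0.05,
                               v_floor = 1e-6) {
  N <- nrow(obs$R); L <- ncol(obs$R)
  if (is.null(obs$sigmaR)) {
    mean_depth <- rowMeans(obs$R)
    obs$sigmaR <- matrix(pmax(v_floor, mean_depth * dispersion),
                         nrow = N, ncol = L)
  }
  if (is.null(obs$sigmaB)) {
    if (!is.null(obs$A)) {
      tot <- matrix(obs$A[, , 1] + obs$A[, , 2], N, L)
    } else if (!is.null(snp_counts)) {
      tot <- as.matrix(snp_counts)
    } else {
      stopf("fallback_variances: need A or snp_counts for BAF variances")
    }
    obs$sigmaB <- pmax(0.25 / pmax(tot, 1), v_floor)
  }
  obs
}

n_cells <- function(obs) nrow(obs$R)

## ---- TSV readers/writers --------------------------------------------------

read_matrix_tsv <- function(path, segments, what = path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "cell_id")
    stopf("%s: first column must be cell_id", what)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (ncol(m) != n_segments(segments))
    stopf("%s: %d segment columns but segment table has %d rows",
          what, ncol(m), n_segments(segments))
  rownames(m) <- df$cell_id
  storage.mode(m) <- "double"
  m
}

write_matrix_tsv <- function(m, segments, cell_ids, path, digits = 8) {
  df <- data.frame(cell_id = cell_ids,
                   signif(m, digits = digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("cell_id", segment_labels(segments))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an observation set from a directory of TSV matrices
#'
#' Expects `R.tsv` plus either `B.tsv` or `A_hap1.tsv`/`A_hap2.tsv`, and
#' optionally `sigmaR.tsv`, `sigmaB.tsv`, `scaling.tsv`. Each matrix file has
#' a `cell_id` first column and one `chrom:start-end` column per segment.
#' All files must agree on cell ids and dimensions; violations raise errors
#' naming the offending file.
#'
#' @param dir directory containing the TSV files.
#' @param segments an [segment_table()]; read from `dir/segments.tsv` when
#'   omitted.
#' @return An [observation_set()].
#' @export
read_observations <- function(dir, segments = NULL) {
  p <- function(f) file.path(dir, f)
  if (is.null(segments)) segments <- read_segments(p("segments.tsv"))
  R <- read_matrix_tsv(p("R.tsv"), segments, "R.tsv")
  cell_ids <- rownames(R)
  pick <- function(f) {
    if (!file.exists(p(f))) return(NULL)
    m <- read_matrix_tsv(p(f), segments, f)
    if (!identical(rownames(m), cell_ids))
      stopf("%s: cell ids do not match R.tsv", f)
    m
  }
  A <- NULL
  A1 <- pick("A_hap1.tsv"); A2 <- pick("A_hap2.tsv")
  if (!is.null(A1) && !is.null(A2)) {
    A <- array(0, dim = c(nrow(R), ncol(R), 2))
    A[, , 1] <- A1; A[, , 2] <- A2
  }
  scaling <- NULL
  if (file.exists(p("scaling.tsv"))) {
    sc <- utils::read.table(p("scaling.tsv"), header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (!identical(as.character(sc$cell_id), cell_ids))
      stopf("scaling.tsv: cell ids do not match R.tsv")
    scaling <- sc$scaling
  }
  observation_set(R, segments, B = pick("B.tsv"), A = A,
                  sigmaR = pick("sigmaR.tsv"), sigmaB = pick("sigmaB.tsv"),
                  scaling = scaling, cell_ids = cell_ids)
}

#' Write an observation set as TSV matrices
#' @param obs an [observation_set()].
#' @param dir output directory (created if needed).
#' @export
write_observations <- function(obs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_segments(obs$segments, p("segments.tsv"))
  write_matrix_tsv(obs$R, obs$segments, obs$cell_ids, p("R.tsv"))
  write_matrix_tsv(obs$B, obs$segments, obs$cell_ids, p("B.tsv"))
  if (!is.null(obs$A)) {
    write_matrix_tsv(obs$A[, , 1], obs$segments, obs$cell_ids, p("A_hap1.tsv"))
    write_matrix_tsv(obs$A[, , 2], obs$segments, obs$cell_ids, p("A_hap2.tsv"))
  }
  write_matrix_tsv(obs$sigmaR, obs$segments, obs$cell_ids, p("sigmaR.tsv"))
  write_matrix_tsv(obs$sigmaB, obs$segments, obs$cell_ids, p("sigmaB.tsv"))
  utils::write.table(data.frame(cell_id = obs$cell_ids,
                                scaling = signif(obs$scaling, 8)),
                     p("scaling.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}

#' Write per-cell profiles as a long TSV
#'
#' One row per cell and segment with columns `cell_id`, `chromosome`,
#' `start`, `end`, `cn_hap1`, `cn_hap2`; cells in input order, segments by
#' index.
#'
#' @param profiles list of [cn_profile()] objects, one per cell.
#' @param segments segment table.
#' @param cell_ids character vector, one id per profile.
#' @param path output file.
#' @export
write_profiles <- function(profiles, segments, cell_ids, path) {
  if (length(profiles) != length(cell_ids))
    stopf("write_profiles: one profile per cell id required")
  L <- n_segments(segments)
  df <- data.frame(
    cell_id = rep(cell_ids, each = L),
    chromosome = rep(segments$chrom, length(profiles)),
    start = rep(as.integer(segments$start), length(profiles)),
    end = rep(as.integer(segments$end), length(profiles)),
    cn_hap1 = unlist(lapply(profiles, `[[`, "hap1")),
    cn_hap2 = unlist(lapply(profiles, `[[`, "hap2")),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-cell profiles written by [write_profiles()]
#' @param path profile TSV.
#' @param c_max per-haplotype copy number cap.
#' @return list with `profiles` (list of [cn_profile()]) and `cell_ids`.
#' @export
read_profiles <- function(path, c_max = 19L) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ids <- unique(df$cell_id)
  profiles <- lapply(ids, function(id) {
    d <- df[df$cell_id == id, ]
    cn_profile(d$cn_hap1, d$cn_hap2, c_max = c_max)
  })
  list(profiles = profiles, cell_ids = ids)
}

#' Validate an observation directory
#'
#' Reads every matrix in `dir`, running all dimension/sign/consistency
#' checks; returns (invisibly) the parsed observation set or raises the
#' first validation error.
#' @param dir observation directory.
#' @export
validate_observations <- function(dir) {
  obs <- read_observations(dir)
  if (!is.null(obs$A)) {
    tot <- obs$A[, , 1] + obs$A[, , 2]
    ok <- tot == 0 | abs(obs$B - obs$A[, , 2] / pmax(tot, 1)) < 1e-6
    if (!all(ok))
      stopf("B.tsv inconsistent with haplotype counts at %d entries", sum(!ok))
  }
  invisible(obs)
}
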