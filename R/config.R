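#' Run configuration
#'
#' All numeric thresholds of the method in one place, so every operating
#' constant is visible, overridable and testable.  The design choices behind
#' the defaults are discussed in the methods vignette.
#'
#' @param ... named overrides of any default listed below.
#' @return a validated named list of class \code{SporeCallConfig}.
#'
#' @details Key entries:
#' \describe{
#'   \item{min_cds_train (600)}{minimum coding-sequence length (nt) admitted
#'     to the coding training set.}
#'   \item{max_utr_orf (300)}{ORFs at least this long are excised from UTR
#'     training examples.}
#'   \item{kozak_width (11), kozak_order (2)}{translation-start window, ending
#'     at (and including) the ATG.}
#'   \item{cds_order (5), utr_order (5)}{Markov chain orders; the coding chain
#'     is three-periodic.}
#'   \item{exon_ext (2), boundary_max (22)}{splice donor/acceptor windows
#'     extend 2 nt into the adjacent exon, total length at most 22 nt.}
#'   \item{chi_p (0.01)}{chi-square significance level (df = 3) for the
#'     automatic donor/acceptor length fit.}
#'   \item{min_introns_for_fit (50)}{below this many evidenced introns the
#'     boundary fit falls back to \code{default_boundary_intronic} (9) plus
#'     the exonic extension.}
#'   \item{intron_factor (1.1), intron_cap (5000)}{maximum intron length is
#'     \code{ceil(intron_factor * longest evidenced intron)} capped at
#'     \code{intron_cap}; \code{disable_intron_cap = TRUE} removes both the
#'     factor rule and the cap.}
#'   \item{relax_nt (50)}{splice boundaries are allowed within this many nt of
#'     a covering transcript's ends despite coverage.}
#'   \item{min_aa (30), variant_min_aa (10), nested_frac (0.20)}{the three
#'     post-prediction filters.}
#' }
#' @export
sporeCallConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    stranded = TRUE,
    pseudocount = 0.01,
    n_floor_log = log(0.25),
    ## stage-1 model structure
    cds_order = 5L,
    utr_order = 5L,
    utr_shared = TRUE,
    kozak_width = 11L,
    kozak_order = 2L,
    wam_backoff = 8,
    ## training-set construction
    min_cds_train = 600L,
    max_utr_orf = 300L,
    min_candidate_orf = 300L,
    min_cds_len = 93L,
    retrain_iterations = 2L,
    order_reduce_quota = 50,
    duration_bandwidth = NA_integer_,   # NA: max(2, support width / 50)
    duration_floor = 1e-6,
    noncoding_prior_floor = 0.02,
    ## stage-2 intron model
    exon_ext = 2L,
    boundary_max = 22L,
    default_boundary_intronic = 9L,
    chi_p = 0.01,
    min_introns_for_fit = 50L,
    boundary_interior_trim = 22L,
    intron_factor = 1.1,
    intron_cap = 5000L,
    disable_intron_cap = FALSE,
    default_max_intron = 1000L,
    min_intron = 20L,
    min_evidenced_intron = 4L,
    branch_width = 7L,
    branch_window = c(6L, 50L),
    spacer_order = 2L,
    ## stage-2 region selection and decoding
    flank_pad = 200L,
    max_window = 10000L,
    window_overlap = 2500L,
    relax_nt = 50L,
    intergenic_order = 5L,
    intergenic_dur_cap = 500L,
    intergenic_self_p = 0.1,
    intergenic_train_cap = 1000000L,
    ## post-prediction filters
    min_aa = 30L,
    variant_min_aa = 10L,
    variant_overlap_frac = 0.5,
    nested_frac = 0.20,
    verbose = FALSE
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown configuration entries: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  scalars <- c("pseudocount", "min_cds_train", "max_utr_orf", "kozak_width",
               "exon_ext", "boundary_max", "chi_p", "min_introns_for_fit",
               "intron_factor", "intron_cap", "min_intron", "relax_nt",
               "flank_pad", "min_aa", "variant_min_aa", "nested_frac")
  for (nm in scalars)
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0)
      stop("configuration entry '", nm, "' must be a positive scalar")
  if (cfg$pseudocount <= 0) stop("pseudocount must be > 0")
  class(cfg) <- c("SporeCallConfig", "list")
  cfg
}

#' Read a run configuration from a YAML file
#' @param path YAML file of flat key: value pairs (names as in
#'   [sporeCallConfig()]).
#' @return a `SporeCallConfig` list.
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sporeCallConfig, vals)
}

#' Write a run configuration as YAML
#' @param cfg a `SporeCallConfig`.
#' @param path output file.
#' @export
writeConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

.vlog <- function(cfg, ...) {
  if (isTRUE(cfg$verbose)) message(...)
  invisible(NULL)
}
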