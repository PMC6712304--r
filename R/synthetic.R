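# Synthetic paired microbial/molecular datasets with planted associations
# and planted duplicate clusters.  The generator emulates the statistical
# structure the association test assumes: independent samples, independent
# background features, and a configurable number of dependent
# (molecule, microbe) pairs of stated conditional strength.

#' Simulation configuration
#'
#' Defaults describe the calibration conditions used throughout the test
#' suite: 200 independent samples, 100 molecular x 50 microbial features
#' with background presence probability 0.3, and (when planted) pairs with
#' P(molecule present | microbe present) = 0.95 and
#' P(molecule present | microbe absent) = 0.02 — a near-deterministic
#' dependence against an independent background.  Duplicate clusters share a
#' latent presence set thinned by independent dropout, with member m/z
#' jittered around a common center by +/- `mz_jitter` (default 0.004, well
#' inside the 0.01 dedup tolerance).
#'
#' @param n_samples,n_molecules,n_microbes Dimensions of the paired tables.
#' @param background_prob Background per-sample presence probability.
#' @param n_planted Number of planted dependent (molecule, microbe) pairs;
#'   the first `n_planted` molecules pair with the first `n_planted`
#'   microbes.
#' @param planted_prob_present,planted_prob_absent P(molecule present)
#'   given the paired microbe present/absent.
#' @param n_duplicate_clusters,duplicate_cluster_size Planted duplicate
#'   clusters appended after the `n_molecules` base molecules.
#' @param duplicate_dropout Per-member, per-sample probability of dropping a
#'   latent presence.
#' @param mz_jitter Half-width of the within-cluster m/z jitter (Thomson).
#' @param mode `"binary"` (0/1 abundances) or `"continuous"` (log-normal
#'   intensity when present, 0 when absent — LC-MS-style zero inflation).
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity parameters
#'   for continuous mode.
#' @param correlated_background Optional shared latent sample factor: with
#'   probability 0.5 per sample all background probabilities are scaled by
#'   `1.5`, breaking feature independence (off by default; used to
#'   stress-test the decoy FDR estimator).
#' @param seed Integer RNG seed (< 2^31).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 200L, n_molecules = 100L,
                       n_microbes = 50L, background_prob = 0.3,
                       n_planted = 0L, planted_prob_present = 0.95,
                       planted_prob_absent = 0.02,
                       n_duplicate_clusters = 0L,
                       duplicate_cluster_size = 3L,
                       duplicate_dropout = 0.1, mz_jitter = 0.004,
                       mode = c("binary", "continuous"),
                       intensity_meanlog = log(5e4), intensity_sdlog = 1,
                       correlated_background = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  probs <- c(background_prob, planted_prob_present, planted_prob_absent,
             duplicate_dropout)
  if (any(!is.finite(probs) | probs < 0 | probs > 1))
    abort("probabilities must lie in [0, 1]")
  for (nm in c("n_samples", "n_molecules", "n_microbes", "n_planted",
               "n_duplicate_clusters", "duplicate_cluster_size"))
    if (!is_count(get(nm))) abort("`", nm, "` must be a non-negative integer")
  if (n_planted > min(n_molecules, n_microbes))
    abort("`n_planted` exceeds the number of molecules or microbes")
  if (n_samples < 2L) abort("need at least 2 samples")
  if (mz_jitter < 0) abort("`mz_jitter` must be >= 0")
  structure(list(n_samples = as.integer(n_samples),
                 n_molecules = as.integer(n_molecules),
                 n_microbes = as.integer(n_microbes),
                 background_prob = background_prob,
                 n_planted = as.integer(n_planted),
                 planted_prob_present = planted_prob_present,
                 planted_prob_absent = planted_prob_absent,
                 n_duplicate_clusters = as.integer(n_duplicate_clusters),
                 duplicate_cluster_size = as.integer(duplicate_cluster_size),
                 duplicate_dropout = duplicate_dropout,
                 mz_jitter = mz_jitter, mode = mode,
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 correlated_background = isTRUE(correlated_background),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a paired microbial/molecular dataset
#'
#' Fully reproducible from `config$seed`.  Microbial counts are Poisson
#' (mean 20) plus one where present, 0 where absent, so binarizing at
#' `MinCount = 0` recovers the generating presence sets exactly; the same
#' holds for molecular intensities at `MinIntensity = 0`.
#'
#' @param config A [sim_config].
#' @return List with `microbes` and `molecules` ([feature_table]s) and
#'   `truth`: a list with `planted` (tibble `molecule_id`, `microbe_id`)
#'   and `duplicates` (tibble `member_id`, `cluster_id`, `center_mz`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_seed(cf$seed, {
    s_ids <- sprintf("sample_%03d", seq_len(cf$n_samples))
    mic_ids <- sprintf("otu_%03d", seq_len(cf$n_microbes))
    mol_ids <- sprintf("mol_%03d", seq_len(cf$n_molecules))

    bg <- rep(cf$background_prob, cf$n_samples)
    if (cf$correlated_background) {
      boost <- stats::runif(cf$n_samples) < 0.5
      bg[boost] <- pmin(1, bg[boost] * 1.5)
    }
    draw_bg <- function() stats::runif(cf$n_samples) < bg

    mic_pres <- t(vapply(mic_ids, function(i) draw_bg(),
                         logical(cf$n_samples)))
    mol_pres <- matrix(FALSE, cf$n_molecules, cf$n_samples,
                       dimnames = list(mol_ids, s_ids))
    for (i in seq_len(cf$n_molecules)) {
      if (i <= cf$n_planted) {
        p <- ifelse(mic_pres[i, ], cf$planted_prob_present,
                    cf$planted_prob_absent)
        mol_pres[i, ] <- stats::runif(cf$n_samples) < p
      } else {
        mol_pres[i, ] <- draw_bg()
      }
    }
    mol_mz <- stats::runif(cf$n_molecules, 100, 1500)

    dup_truth <- tibble::tibble(member_id = character(),
                                cluster_id = character(),
                                center_mz = numeric())
    if (cf$n_duplicate_clusters > 0L) {
      dup_pres <- list(); dup_mz <- numeric(0)
      for (cidx in seq_len(cf$n_duplicate_clusters)) {
        latent <- draw_bg()
        center <- stats::runif(1, 100, 1500)
        for (j in seq_len(cf$duplicate_cluster_size)) {
          id <- sprintf("dup%02d_%d", cidx, j)
          dup_pres[[id]] <- latent &
            (stats::runif(cf$n_samples) >= cf$duplicate_dropout)
          dup_mz[id] <- center + stats::runif(1, -cf$mz_jitter, cf$mz_jitter)
          dup_truth <- rbind(dup_truth,
                             tibble::tibble(member_id = id,
                                            cluster_id = sprintf("dup%02d", cidx),
                                            center_mz = center))
        }
      }
      mol_pres <- rbind(mol_pres, do.call(rbind, dup_pres))
      mol_mz <- c(mol_mz, unname(dup_mz))
      mol_ids <- rownames(mol_pres)
    }
    dimnames(mic_pres) <- list(mic_ids, s_ids)
    dimnames(mol_pres) <- list(mol_ids, s_ids)

    mic_counts <- matrix(0, nrow(mic_pres), ncol(mic_pres),
                         dimnames = dimnames(mic_pres))
    npres <- sum(mic_pres)
    mic_counts[mic_pres] <- stats::rpois(npres, 20) + 1
    mol_values <- matrix(0, nrow(mol_pres), ncol(mol_pres),
                         dimnames = dimnames(mol_pres))
    if (cf$mode == "continuous") {
      mol_values[mol_pres] <- stats::rlnorm(sum(mol_pres),
                                            cf$intensity_meanlog,
                                            cf$intensity_sdlog)
    } else {
      mol_values[mol_pres] <- 1
    }

    planted <- tibble::tibble(
      molecule_id = sprintf("mol_%03d", seq_len(cf$n_planted)),
      microbe_id = sprintf("otu_%03d", seq_len(cf$n_planted)))

    list(microbes = feature_table(mic_counts, kind = "microbial"),
         molecules = feature_table(mol_values, kind = "molecular",
                                   mz = mol_mz),
         truth = list(planted = planted, duplicates = dup_truth),
         config = cf)
  })
}

#' Score a scan against the simulation truth
#'
#' @param edges Edge table from [association_scan()].
#' @param truth The `truth` element of [simulate_dataset()] output (or its
#'   `planted` tibble).
#' @return List with `recall` (fraction of planted pairs recovered),
#'   `empirical_fdr` (fraction of reported edges that are not planted; 0
#'   when no edges are reported), `n_edges`, `n_planted`.
#' @export
evaluate_edges <- function(edges, truth) {
  planted <- if (is.data.frame(truth)) truth else truth$planted
  key <- function(mol, mic) paste(mol, mic, sep = "\r")
  pk <- key(planted$molecule_id, planted$microbe_id)
  ek <- key(edges$molecule_id, edges$microbe_id)
  recall <- if (length(pk) == 0L) NA_real_ else mean(pk %in% ek)
  efdr <- if (length(ek) == 0L) 0 else mean(!ek %in% pk)
  list(recall = recall, empirical_fdr = efdr,
       n_edges = length(ek), n_planted = length(pk))
}
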