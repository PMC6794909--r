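# Config-driven orchestration of the full analysis sequence.

#' Build a pipeline run configuration
#'
#' @param study A [study_dataset], or `NULL` to generate one.
#' @param generator A [generator_spec()] used when `study` is `NULL`.
#' @param exclusions Named list `bone_id -> landmark_ids` removed before
#'   analysis (merged with the dataset's own lists).
#' @param pc_threshold Fraction of shape variance the retained PCs must
#'   explain (default 0.90).
#' @param n_perm Permutations for all permutation tests (default 999).
#' @param n_boot Bootstrap replicates for index intervals (default 999).
#' @param alpha Significance level (default 0.05).
#' @param pair_sets Bone-pair table for the integration network
#'   (default [default_pair_sets()]).
#' @param pool Pool mules and hinnies into one hybrid group (default `TRUE`).
#' @param run_network Run the covariation network stage (default `TRUE`).
#' @param seed Global seed, deterministically split per stage and bone.
#' @return Object of class `run_config`.
#' @export
run_config <- function(study = NULL, generator = NULL, exclusions = list(),
                       pc_threshold = 0.90, n_perm = 999L, n_boot = 999L,
                       alpha = 0.05, pair_sets = NULL, pool = TRUE,
                       run_network = TRUE, seed = 1L) {
  if (is.null(study) && is.null(generator))
    stop_mh("provide a study or a generator spec")
  if (pc_threshold <= 0 || pc_threshold > 1)
    stop_mh("pc_threshold must be in (0, 1]")
  if (alpha <= 0 || alpha >= 1) stop_mh("alpha must be in (0, 1)")
  structure(list(study = study, generator = generator,
                 exclusions = exclusions, pc_threshold = pc_threshold,
                 n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
                 alpha = alpha, pair_sets = pair_sets, pool = pool,
                 run_network = run_network, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML file may carry scalar settings (`pc_threshold`, `n_perm`,
#' `n_boot`, `alpha`, `seed`, `pool`, `run_network`), `exclusions`
#' (mapping bone -> landmark ids), `generator` (arguments to
#' [generator_spec()], with group counts under the key `n_per_group` --
#' YAML parses a bare `n` as a boolean), input paths (`landmarks`: list of
#' `{path, format, bone}` entries; `metadata`: specimen CSV path), and
#' `pair_sets` (list of `{bone_a, bone_b, pair_set}`).
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  study <- NULL
  if (!is.null(y$landmarks)) {
    if (is.null(y$metadata)) stop_mh("config provides landmarks but no metadata")
    configs <- list()
    for (entry in y$landmarks) {
      configs <- c(configs,
                   read_landmarks(entry$path, entry$format %||% "csv",
                                  bone_id = entry$bone %||% "bone"))
    }
    specimens <- utils::read.csv(y$metadata, stringsAsFactors = FALSE)
    study <- study_dataset(specimens, configs)
  }
  gen <- NULL
  if (!is.null(y$generator)) {
    args <- y$generator
    # YAML 1.1 parses a bare `n` key as a boolean; accept `n_per_group`
    if (!is.null(args$n_per_group)) { args$n <- args$n_per_group; args$n_per_group <- NULL }
    if ("FALSE" %in% names(args) && is.null(args$n)) {
      args$n <- args[["FALSE"]]; args[["FALSE"]] <- NULL
    }
    for (nm in c("n", "bones", "size_log_mean", "size_log_sd",
                 "divergence", "f", "t", "noise_sd", "slope"))
      if (!is.null(args[[nm]]) && is.list(args[[nm]]))
        args[[nm]] <- unlist(args[[nm]])
    if (!is.null(args$integration))
      args$integration <- do.call(rbind,
                                  lapply(args$integration, as.data.frame))
    gen <- do.call(generator_spec, args)
  }
  pair_sets <- NULL
  if (!is.null(y$pair_sets))
    pair_sets <- do.call(rbind, lapply(y$pair_sets, as.data.frame))
  run_config(study = study, generator = gen,
             exclusions = y$exclusions %||% list(),
             pc_threshold = y$pc_threshold %||% 0.90,
             n_perm = y$n_perm %||% 999L, n_boot = y$n_boot %||% 999L,
             alpha = y$alpha %||% 0.05, pair_sets = pair_sets,
             pool = y$pool %||% TRUE, run_network = y$run_network %||% TRUE,
             seed = y$seed %||% 1L)
}

#' Run the full analysis pipeline
#'
#' Per bone: GPA, PCA (with PC retention at the configured variance
#' threshold), pairwise MANOVA between groups, two-way species-by-sex MANOVA
#' (with an automatic sex-stratified rerun of the ordination and hybrid
#' indices for bones whose interaction is significant), Procrustes-variance
#' disparity with permutation comparisons, size ANOVA on log10 centroid size,
#' allometry (multivariate shape-on-size regression and slope homogeneity),
#' and transgression/dominance indices with bootstrap intervals. Across bones:
#' the covariation network and the between-group comparison of integration
#' effect sizes.
#'
#' All randomness derives from the single configured seed, split
#' deterministically per stage and bone, so a rerun with the same
#' configuration reproduces the report exactly.
#'
#' @param config A [run_config()].
#' @return Object of class `pipeline_report`: `tables` (named list of data
#'   frames), `manifest` (settings and per-stage seeds), `study` (the analyzed
#'   dataset).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  study <- config$study
  if (is.null(study)) study <- generate_study(config$generator)$study
  study <- pool_hybrids(study, pool = config$pool)
  excl <- config$exclusions
  if (length(excl)) study <- apply_exclusions(study, excl)
  study <- apply_exclusions(study)

  bones <- names(study$bones)
  groups <- sort(unique(study$specimens$group))
  has_three <- all(c("donkey", "horse", "hybrid") %in% groups)
  seed0 <- config$seed
  stage_seeds <- list()

  gpa_summary <- list(); pca_summary <- list(); pca_scores <- list()
  manova_pw <- list(); manova_2w <- list(); disparity_rows <- list()
  disparity_pw <- list(); size_rows <- list(); size_pw <- list()
  allometry_rows <- list(); indices_rows <- list(); indices_sex <- list()

  for (bi in seq_along(bones)) {
    bone <- bones[bi]
    stage <- function(what, off) {
      s <- derive_seed(seed0, bi * 100L + off)
      stage_seeds[[paste(bone, what, sep = ".")]] <<- s
      s
    }
    smp <- bone_sample(study, bone)
    fit <- tryCatch(gpa(smp$coords),
                    error = function(e) stop_mh("stage gpa/", bone, ": ",
                                                conditionMessage(e)))
    labels <- smp$specimens$group
    log_cs <- log10(fit$csize)
    gpa_summary[[bone]] <- data.frame(bone = bone, n = dim(fit$aligned)[3],
                                      k = dim(fit$aligned)[1],
                                      iterations = fit$iterations,
                                      converged = fit$converged)
    pca <- shape_pca(fit$shape)
    keep <- retain_pcs(pca, config$pc_threshold)
    scores <- pca$scores[, keep, drop = FALSE]
    pca_summary[[bone]] <- data.frame(
      bone = bone, n_pcs = length(keep),
      var_pc1 = pca$variance_fractions[1],
      var_pc2 = if (length(pca$variance_fractions) > 1)
        pca$variance_fractions[2] else NA_real_,
      var_retained = sum(pca$variance_fractions[keep]))
    pca_scores[[bone]] <- data.frame(
      bone = bone, specimen_id = smp$specimens$specimen_id, group = labels,
      PC1 = pca$scores[, 1],
      PC2 = if (ncol(pca$scores) > 1) pca$scores[, 2] else NA_real_,
      row.names = NULL)

    pw <- tryCatch(cbind(bone = bone,
                         pairwise_manova(scores, labels)),
                   error = function(e) NULL)
    manova_pw[[bone]] <- pw

    tw <- NULL
    sex <- smp$specimens$sex
    if (!is.null(sex) &&
        length(unique(stats::na.omit(sex[sex != "gelding"]))) >= 2) {
      tw <- tryCatch(cbind(bone = bone,
                           two_way_manova(scores, labels, sex)),
                     error = function(e) NULL)
    }
    manova_2w[[bone]] <- tw
    interaction_sig <- !is.null(tw) &&
      any(tw$term == "interaction" & tw$p < config$alpha, na.rm = TRUE)

    disp <- disparity_test(fit$shape, labels, n_perm = config$n_perm,
                           seed = stage("disparity", 1L))
    disparity_rows[[bone]] <- data.frame(bone = bone,
                                         group = names(disp$variances),
                                         variance = unname(disp$variances),
                                         row.names = NULL)
    disparity_pw[[bone]] <- cbind(bone = bone, disp$pairwise)

    sz <- size_anova(log_cs, labels)
    size_rows[[bone]] <- data.frame(bone = bone, F = sz$F, p = sz$p)
    size_pw[[bone]] <- cbind(bone = bone, sz$pairwise)

    reg <- shape_size_regression(fit$shape, log_cs, n_perm = config$n_perm,
                                 seed = stage("allometry", 2L))
    hom <- slope_homogeneity(fit$shape, log_cs, labels,
                             n_perm = config$n_perm,
                             seed = stage("slopes", 3L))
    allometry_rows[[bone]] <- data.frame(bone = bone,
                                         r_squared = reg$r_squared,
                                         p = reg$p_value,
                                         homogeneity_p = hom$p_value)

    if (has_three) {
      hi <- hybrid_indices_boot(fit$shape, labels, n_boot = config$n_boot,
                                seed = stage("indices", 4L))
      indices_rows[[bone]] <- data.frame(
        bone = bone, d_DHo = hi$d_DHo, d_DHy = hi$d_DHy, d_HoHy = hi$d_HoHy,
        transgression_pct = hi$transgression_pct,
        transgression_lo = hi$transgression_ci[1],
        transgression_hi = hi$transgression_ci[2],
        dominance_pct = hi$dominance_pct,
        dominance_lo = hi$dominance_ci[1],
        dominance_hi = hi$dominance_ci[2],
        sex_stratified = interaction_sig)
      if (interaction_sig) {
        for (s in c("female", "male")) {
          sel <- !is.na(sex) & sex == s
          if (all(table(factor(labels[sel],
                               c("donkey", "horse", "hybrid"))) >= 2)) {
            his <- hybrid_indices(fit$shape[sel, , drop = FALSE], labels[sel])
            indices_sex[[paste(bone, s)]] <- data.frame(
              bone = bone, sex = s,
              transgression_pct = his$transgression_pct,
              dominance_pct = his$dominance_pct)
          }
        }
      }
    }
  }

  network <- NULL; zcomp <- NULL
  if (config$run_network && length(bones) >= 2L) {
    ps <- config$pair_sets %||% default_pair_sets(bones)
    ps <- ps[ps$bone_a %in% bones & ps$bone_b %in% bones, , drop = FALSE]
    if (nrow(ps)) {
      net <- suppressWarnings(
        covariation_network(study, pair_sets = ps,
                            n_perm = config$n_perm,
                            seed = derive_seed(seed0, 999999L),
                            alpha = config$alpha))
      stage_seeds[["network"]] <- derive_seed(seed0, 999999L)
      network <- net$edges
      zcomp <- compare_network_effects(net)
    }
  }

  bindr <- function(lst) {
    lst <- Filter(Negate(is.null), lst)
    if (length(lst)) { out <- do.call(rbind, lst); rownames(out) <- NULL; out }
    else NULL
  }
  tables <- list(gpa = bindr(gpa_summary), pca = bindr(pca_summary),
                 pca_scores = bindr(pca_scores),
                 manova_pairwise = bindr(manova_pw),
                 manova_two_way = bindr(manova_2w),
                 disparity = bindr(disparity_rows),
                 disparity_pairwise = bindr(disparity_pw),
                 size_anova = bindr(size_rows),
                 size_pairwise = bindr(size_pw),
                 allometry = bindr(allometry_rows),
                 hybrid_indices = bindr(indices_rows),
                 hybrid_indices_by_sex = bindr(indices_sex),
                 integration_network = network,
                 z_comparison = zcomp)
  manifest <- list(seed = seed0, pc_threshold = config$pc_threshold,
                   n_perm = config$n_perm, n_boot = config$n_boot,
                   alpha = config$alpha, pool = config$pool,
                   bones = bones, groups = groups,
                   stage_seeds = stage_seeds,
                   config_hash = config_hash(config))
  structure(list(tables = tables, manifest = manifest, study = study),
            class = "pipeline_report")
}

config_hash <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "study")]),
               collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% 2^31)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (seed", x$manifest$seed, ", hash",
      x$manifest$config_hash, ")\n")
  cat("  bones:", length(x$manifest$bones),
      " groups:", paste(x$manifest$groups, collapse = ", "), "\n")
  for (nm in names(x$tables))
    if (!is.null(x$tables[[nm]]))
      cat(sprintf("  table %-22s %d rows\n", nm, nrow(x$tables[[nm]])))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' One CSV per table plus a JSON manifest recording every seed, permutation
#' count and setting.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$tables)) {
    tab <- report$tables[[nm]]
    if (!is.null(tab))
      utils::write.csv(tab, file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
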