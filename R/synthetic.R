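#' Specification of a synthetic phenotyping cohort
#'
#' Describes a cohort with the statistical structure the pipeline assumes:
#' a genotype factor with a gene-dosage ordering (WT/Het/Homo), two sexes
#' with unbalanced group sizes, quantitative test readouts partly organized
#' in named test groups, planted effects and missing cells.
#'
#' Defaults emulate a mid-size mouse phenotyping cohort: 112 animals
#' (57 females / 55 males; 36/39/37 per genotype), 12 quantitative traits of
#' which 3 carry an additive dosage effect (shift `delta_linear` per mutant
#' allele, in units of the within-stratum SD), 1 carries a non-monotone
#' effect (heterozygotes deviate by `delta_nonlinear` while both homozygous
#' classes share a mean — invisible to any WT-vs-Homo linear contrast), and
#' 8 are pure noise. A mild sex effect is planted on the linear-signal
#' traits. Missingness is 2% MCAR by default (`mar_by_sex` doubles the rate
#' in males and removes it in females to stress imputation).
#'
#' @param group_sizes 3x2 integer matrix (genotype x sex) of stratum sizes;
#'   dimnames give the level labels.
#' @param n_signal_linear,n_signal_nonlinear,n_noise Trait counts.
#' @param delta_linear Additive shift per dosage step (WT=0, Het=1, Homo=2).
#' @param delta_nonlinear Heterozygote-specific shift of the non-monotone
#'   traits.
#' @param sex_effect Additive shift for males on the linear-signal traits.
#' @param noise_sd Within-stratum standard deviation of every trait.
#' @param missing_rate Fraction of trait cells set missing, in [0, 1).
#' @param mar_by_sex Make missingness depend on sex (males only).
#' @param heavy_tail Draw the last noise trait log-normal instead of normal.
#' @param seed Integer seed; the cohort is a deterministic function of it.
#' @return An object of class `pd_synthetic_spec`.
#' @export
synthetic_spec <- function(group_sizes = NULL,
                           n_signal_linear = 3L,
                           n_signal_nonlinear = 1L,
                           n_noise = 8L,
                           delta_linear = 0.8,
                           delta_nonlinear = 1.2,
                           sex_effect = 0.5,
                           noise_sd = 1,
                           missing_rate = 0.02,
                           mar_by_sex = FALSE,
                           heavy_tail = FALSE,
                           seed = 1L) {
  if (is.null(group_sizes)) {
    group_sizes <- matrix(c(18L, 20L, 19L, 18L, 19L, 18L), nrow = 3,
                          dimnames = list(c("WT", "Het", "Homo"),
                                          c("F", "M")))
  }
  stopifnot(is.matrix(group_sizes), all(group_sizes >= 0),
            missing_rate >= 0, missing_rate < 1, noise_sd > 0)
  if (sum(group_sizes) < 1L) stop("pd_infeasible_spec: zero individuals")
  structure(list(group_sizes = group_sizes,
                 n_signal_linear = as.integer(n_signal_linear),
                 n_signal_nonlinear = as.integer(n_signal_nonlinear),
                 n_noise = as.integer(n_noise),
                 delta_linear = delta_linear,
                 delta_nonlinear = delta_nonlinear,
                 sex_effect = sex_effect,
                 noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 mar_by_sex = isTRUE(mar_by_sex),
                 heavy_tail = isTRUE(heavy_tail),
                 seed = as.integer(seed)),
            class = "pd_synthetic_spec")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a [pheno_table] according to a [synthetic_spec()] together with a
#' ground-truth record naming the planted-signal variables and their effect
#' sizes. Traits are drawn normal within genotype-by-sex stratum; part of the
#' traits share `"::"` test-group labels so grouped and ungrouped variables
#' both occur. A fixed seed yields an identical table.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `table` (a `pheno_table`) and `truth` (list:
#'   `signal_linear`, `signal_nonlinear`, `noise`, effect sizes, stratum
#'   means).
#' @examples
#' cohort <- generate_cohort(synthetic_spec(seed = 42))
#' cohort$table
#' cohort$truth$signal_linear
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "pd_synthetic_spec"))
  set.seed(spec$seed)
  gs <- spec$group_sizes
  genos <- rownames(gs); sexes <- colnames(gs)
  dose <- stats::setNames(seq_along(genos) - 1L, genos)

  genotype <- character(0); sex <- character(0)
  for (g in genos) for (s in sexes) {
    genotype <- c(genotype, rep(g, gs[g, s]))
    sex <- c(sex, rep(s, gs[g, s]))
  }
  n <- length(genotype)

  lin_names <- if (spec$n_signal_linear) paste0("SigLin", seq_len(spec$n_signal_linear)) else character(0)
  nl_names <- if (spec$n_signal_nonlinear) paste0("SigNonLin", seq_len(spec$n_signal_nonlinear)) else character(0)
  noise_names <- if (spec$n_noise) paste0("Noise", seq_len(spec$n_noise)) else character(0)

  traits <- list()
  for (v in lin_names) {
    mu <- spec$delta_linear * dose[genotype] +
      spec$sex_effect * (sex == sexes[length(sexes)])
    traits[[v]] <- stats::rnorm(n, mu, spec$noise_sd)
  }
  for (v in nl_names) {
    # non-monotone: only the middle (heterozygous) class is shifted
    mu <- spec$delta_nonlinear * (dose[genotype] == 1L)
    traits[[v]] <- stats::rnorm(n, mu, spec$noise_sd)
  }
  for (i in seq_along(noise_names)) {
    v <- noise_names[i]
    if (spec$heavy_tail && i == length(noise_names)) {
      traits[[v]] <- stats::rlnorm(n, 0, spec$noise_sd)
    } else {
      traits[[v]] <- stats::rnorm(n, 0, spec$noise_sd)
    }
  }

  data <- data.frame(genotype = genotype, sex = sex, traits,
                     stringsAsFactors = FALSE, check.names = FALSE)
  trait_names <- c(lin_names, nl_names, noise_names)

  # group part of the traits into shared behavioural tests, pairwise
  groups <- stats::setNames(rep(NA_character_, ncol(data)), names(data))
  pairable <- trait_names[seq_len(min(length(trait_names), 6L))]
  if (length(pairable) >= 2L) {
    for (i in seq_len(length(pairable) %/% 2L)) {
      groups[pairable[c(2L * i - 1L, 2L * i)]] <- paste0("Test", LETTERS[i])
    }
  }

  if (spec$missing_rate > 0 && length(trait_names)) {
    for (v in trait_names) {
      rate <- if (spec$mar_by_sex) {
        ifelse(sex == sexes[length(sexes)], 2 * spec$missing_rate, 0)
      } else rep(spec$missing_rate, n)
      drop <- stats::runif(n) < rate
      # keep at least 3 observed values per stratum so imputation stays feasible
      data[[v]][drop] <- NA
    }
  }

  roles <- stats::setNames(rep("predictor", ncol(data)), names(data))
  roles[["genotype"]] <- "dependent"
  roles[["sex"]] <- "conditioning"
  types <- stats::setNames(rep("quantitative", ncol(data)), names(data))
  types[c("genotype", "sex")] <- "qualitative"

  tab <- pheno_table(data, sprintf("IND%03d", seq_len(n)), roles, types, groups)
  truth <- list(signal_linear = lin_names,
                signal_nonlinear = nl_names,
                noise = noise_names,
                delta_linear = spec$delta_linear,
                delta_nonlinear = spec$delta_nonlinear,
                sex_effect = spec$sex_effect,
                dose = dose,
                stratum_means = {
                  mu <- outer(spec$delta_linear * dose,
                              stats::setNames(c(0, spec$sex_effect), sexes), "+")
                  mu
                })
  list(table = tab, truth = truth)
}
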