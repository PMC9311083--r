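#' Configuration of the synthetic meta-analytic data generator
#'
#' Describes a fully specified generative model in the group-summary schema
#' so that every pipeline stage (effect sizes, phylogeny, meta-regression)
#' can be validated against known truth. The hierarchy mirrors the fitted
#' model: a Yule species phylogeny with Grafen-correlated phylogenetic
#' effects, independent species, study and experiment effects, a sex(male)
#' deviation from the female mean effect, and sex-specific residual
#' heterogeneity per contrast. Group means are back-constructed from each
#' contrast's true standardised effect so that Hedges' d recovers it up to
#' sampling error consistent with its variance formula.
#'
#' The defaults emulate a cold-resistance-like trait: true female mean
#' d = 1.76 with a male deviation of -0.8, heterogeneity dominated by the
#' experiment and residual levels, group sizes n ~ DiscreteUniform(5, 50),
#' baseline trait mean 100 with coefficient of variation 0.3.
#'
#' @param seed RNG seed; the whole generated dataset is a deterministic
#'   function of the config.
#' @param n_species Number of species (tips of the simulated phylogeny).
#' @param studies_per_species,experiments_per_study Design counts.
#' @param levels_per_experiment Treatment levels per experiment (2-4).
#' @param trait_class One of [trait_classes()].
#' @param treatment_type Treatment category label for generated rows.
#' @param d_female True mean standardised effect for females.
#' @param d_sex_male True sex(male) deviation added for males.
#' @param sigma2_species,sigma2_phylo,sigma2_study,sigma2_experiment
#'   Variance components of the latent effect hierarchy.
#' @param sigma2_resid_f,sigma2_resid_m Sex-specific residual heterogeneity
#'   per contrast.
#' @param n_range Integer bounds of the discrete-uniform group sample size.
#' @param baseline_mean Baseline (warm/reference) trait mean.
#' @param cv Baseline coefficient of variation of the trait.
#' @param sd_lognormal_sd Log-scale spread of group SDs around the baseline
#'   CV.
#' @param temperatures Temperature grid from which level temperatures are
#'   taken (coldest to warmest; the first `levels_per_experiment` distinct
#'   values are used per experiment).
#' @param cv_ratio Multiplicative inflation of the SD in the coldest
#'   treatment (1 = no CV difference between treatments).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_species = 30L, studies_per_species = 1L,
                         experiments_per_study = 2L, levels_per_experiment = 2L,
                         trait_class = "cold_resistance",
                         treatment_type = "acclimation",
                         d_female = 1.76, d_sex_male = -0.8,
                         sigma2_species = 0.05, sigma2_phylo = 0.05,
                         sigma2_study = 0.2, sigma2_experiment = 0.3,
                         sigma2_resid_f = 0.8, sigma2_resid_m = 0.8,
                         n_range = c(5L, 50L), baseline_mean = 100,
                         cv = 0.3, sd_lognormal_sd = 0.2,
                         temperatures = c(15, 20, 25, 30),
                         cv_ratio = 1) {
  if (levels_per_experiment < 2 || levels_per_experiment > 4)
    stop("levels_per_experiment must be 2-4", call. = FALSE)
  if (!trait_class %in% trait_classes())
    stop("unknown trait class: ", trait_class, call. = FALSE)
  vars <- c(sigma2_species, sigma2_phylo, sigma2_study, sigma2_experiment,
            sigma2_resid_f, sigma2_resid_m)
  if (any(vars < 0)) stop("variance components must be >= 0", call. = FALSE)
  if (length(unique(temperatures)) < levels_per_experiment)
    stop("need at least levels_per_experiment distinct temperatures", call. = FALSE)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic meta-analytic dataset with known truth
#'
#' Simulates a Yule phylogeny (`ape::rphylo`), draws phylogenetic species
#' effects from `Normal(0, sigma2_phylo * A_grafen)` plus independent
#' species/study/experiment effects, forms each contrast's true Hedges' d
#' (female mean + sex deviation + latent effects + sex-specific residual),
#' and back-constructs the group summaries: the reference extreme level
#' keeps the baseline mean and the opposite extreme is offset by
#' `d_true * SD`, oriented so that the trait-class direction convention
#' recovers `+d_true`. With more than two levels the standardised offsets
#' grade linearly with temperature rank, so sub-range contrasts have
#' proportionally smaller true effects (all recorded in the truth table).
#' Observed group means and SDs carry exact sampling noise
#' (`Normal(mean, sd^2/n)` and scaled chi-square), so computed effect sizes
#' scatter around truth with variance matching the Hedges' d formula.
#'
#' @param config A [synth_config()].
#' @return A list: `groups` (group-summary tibble in the [read_dataset()]
#'   schema), `tree` (`ape::phylo`), and `truth` (list holding the config,
#'   the latent effects, and a per-contrast tibble of true effects).
#' @export
synth_generate <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  ns <- config$n_species
  tree <- ape::rphylo(ns, birth = 1, death = 0)
  tree$tip.label <- sprintf("species_%03d", seq_len(ns))
  A <- grafen_correlation(tree)
  species <- rownames(A)

  u_phylo <- if (config$sigma2_phylo > 0)
    as.vector(t(chol(A + diag(1e-10, ns))) %*% stats::rnorm(ns)) *
    sqrt(config$sigma2_phylo) else rep(0, ns)
  u_species <- stats::rnorm(ns, 0, sqrt(config$sigma2_species))
  names(u_phylo) <- names(u_species) <- species

  L <- config$levels_per_experiment
  temps <- sort(unique(config$temperatures))[seq_len(L)]
  warm_minus_cold <- config$trait_class %in% WARM_MINUS_COLD
  sd0 <- config$cv * config$baseline_mean

  rows <- list()
  truth_rows <- list()
  ri <- ti <- 0L
  for (is in seq_len(ns)) {
    for (ist in seq_len(config$studies_per_species)) {
      study_id <- sprintf("study_%03d_%d", is, ist)
      u_study <- stats::rnorm(1, 0, sqrt(config$sigma2_study))
      for (ie in seq_len(config$experiments_per_study)) {
        exp_id <- sprintf("exp_%d", ie)
        u_exp <- stats::rnorm(1, 0, sqrt(config$sigma2_experiment))
        for (sex in c("F", "M")) {
          s2r <- if (sex == "F") config$sigma2_resid_f else config$sigma2_resid_m
          d_true <- config$d_female +
            (sex == "M") * config$d_sex_male +
            u_species[[is]] + u_phylo[[is]] + u_study + u_exp +
            stats::rnorm(1, 0, sqrt(s2r))
          # standardised level offsets: 0 at the reference extreme, d_true at
          # the other, varying linearly with temperature rank. The offset is
          # attached to the colder end for cold-minus-warm classes and to the
          # warmer end for warm-minus-cold classes, so the direction
          # convention recovers +d_true for the full-range contrast.
          frac <- (seq_len(L) - 1) / (L - 1)           # 0 = coldest ... 1 = warmest
          offs <- if (warm_minus_cold) d_true * frac else d_true * rev(frac)
          # one trait scale per experiment x sex: the standardiser of the
          # back-constructed offsets, so computed d is unbiased for d_true
          sd_true <- sd0 * exp(stats::rnorm(1, 0, config$sd_lognormal_sd))
          n_choices <- config$n_range[1]:config$n_range[2]
          for (il in seq_len(L)) {
            n_i <- if (length(n_choices) == 1L) n_choices
            else sample(n_choices, 1)
            sd_lvl <- if (il == 1) sd_true * config$cv_ratio else sd_true
            mu_true <- config$baseline_mean + offs[il] * sd_true
            m_obs <- stats::rnorm(1, mu_true, sd_lvl / sqrt(n_i))
            sd_obs <- sd_lvl * sqrt(stats::rchisq(1, n_i - 1) / (n_i - 1))
            ri <- ri + 1L
            rows[[ri]] <- tibble::tibble(
              study_id = study_id, experiment_id = exp_id,
              species = species[is], trait_class = config$trait_class,
              trait_name = config$trait_class,
              treatment_type = config$treatment_type,
              treatment_level_id = sprintf("L%d", il),
              temperature = temps[il], sex = sex,
              mean = m_obs, sd = sd_obs, n = n_i)
          }
          for (pr in utils::combn(seq_len(L), 2, simplify = FALSE)) {
            ti <- ti + 1L
            truth_rows[[ti]] <- tibble::tibble(
              study_id = study_id, experiment_id = exp_id,
              species = species[is], sex = sex,
              level_1 = sprintf("L%d", if (warm_minus_cold) max(pr) else min(pr)),
              level_2 = sprintf("L%d", if (warm_minus_cold) min(pr) else max(pr)),
              d_true = abs(offs[pr[2]] - offs[pr[1]]) * sign(d_true))
          }
        }
      }
    }
  }
  list(
    groups = dplyr::bind_rows(rows),
    tree = tree,
    truth = list(config = config,
                 u_species = u_species, u_phylo = u_phylo,
                 contrasts = dplyr::bind_rows(truth_rows))
  )
}
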