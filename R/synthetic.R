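#' Specification of a class-structured synthetic expression dataset
#'
#' Describes a log-normal expression generator with planted class signal:
#' within each pathway an informative subset of genes receives
#' class-dependent log-space means (class `c` gets mean `sign_m * c *
#' effect_size` for a gene-specific random sign), while the remaining
#' noise genes are class-independent. Values are drawn as
#' `exp(N(mean, noise_sd^2))`, mimicking the positivity and skew of
#' FPKM-like data, then zeroed independently with probability
#' `zero_inflation_rate`.
#'
#' @param n_classes Number of phenotype classes.
#' @param n_samples_per_class Samples per class.
#' @param n_pathways Number of (disjoint) pathways.
#' @param genes_per_pathway Member genes per pathway.
#' @param informative_fraction Fraction of each pathway's genes carrying
#'   class signal (at least one gene).
#' @param effect_size Log-space spacing between consecutive class means
#'   (delta); `0` produces data with no class signal.
#' @param noise_sd Log-space standard deviation (sigma); the
#'   signal-to-noise ratio is `effect_size / noise_sd`.
#' @param zero_inflation_rate Probability that any value is replaced by
#'   zero (dropout).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_classes = 3L, n_samples_per_class = 30L,
                            n_pathways = 10L, genes_per_pathway = 10L,
                            informative_fraction = 0.3, effect_size = 1,
                            noise_sd = 0.2, zero_inflation_rate = 0,
                            seed = 1L) {
  stopifnot(n_classes >= 1L, n_samples_per_class >= 1L, n_pathways >= 1L,
            genes_per_pathway >= 1L,
            informative_fraction >= 0, informative_fraction <= 1,
            effect_size >= 0, noise_sd > 0,
            zero_inflation_rate >= 0, zero_inflation_rate <= 1)
  structure(list(n_classes = as.integer(n_classes),
                 n_samples_per_class = as.integer(n_samples_per_class),
                 n_pathways = as.integer(n_pathways),
                 genes_per_pathway = as.integer(genes_per_pathway),
                 informative_fraction = informative_fraction,
                 effect_size = effect_size, noise_sd = noise_sd,
                 zero_inflation_rate = zero_inflation_rate,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Generate a synthetic expression dataset with known structure
#'
#' @param spec A [simulation_spec()].
#' @return List with `expression` (genes x samples matrix), `gene_sets`
#'   (one disjoint set per pathway), `labels` (named factor) and `truth`,
#'   a `data.frame` marking each gene's pathway, informative status and
#'   signal sign.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  C <- spec$n_classes
  S <- C * spec$n_samples_per_class
  G <- spec$genes_per_pathway
  n_inf <- max(1L, as.integer(round_half_away(spec$informative_fraction * G)))

  sample_ids <- sprintf("s%03d", seq_len(S))
  class_ids <- sprintf("c%d", seq_len(C))
  y <- rep(seq_len(C), each = spec$n_samples_per_class)
  labels <- phenotype_labels(stats::setNames(class_ids[y], sample_ids))

  with_seed(spec$seed, {
    expr <- NULL; sets <- list(); truth <- list()
    for (p in seq_len(spec$n_pathways)) {
      genes <- sprintf("pw%02d_g%02d", p, seq_len(G))
      informative <- sort(sample.int(G, n_inf))
      sign <- integer(G)
      sign[informative] <- sample(c(-1L, 1L), n_inf, replace = TRUE)
      mu <- matrix(0, nrow = G, ncol = S)
      for (m in informative) {
        mu[m, ] <- sign[m] * y * spec$effect_size
      }
      vals <- exp(mu + matrix(stats::rnorm(G * S, sd = spec$noise_sd),
                              nrow = G))
      if (spec$zero_inflation_rate > 0) {
        drop <- matrix(stats::runif(G * S) < spec$zero_inflation_rate,
                       nrow = G)
        vals[drop] <- 0
      }
      rownames(vals) <- genes
      expr <- rbind(expr, vals)
      sets[[sprintf("pw%02d", p)]] <- genes
      truth[[p]] <- data.frame(
        pathway_id = sprintf("pw%02d", p), gene_id = genes,
        informative = seq_len(G) %in% informative, sign = sign,
        stringsAsFactors = FALSE)
    }
    colnames(expr) <- sample_ids
    attr(sets, "description") <- stats::setNames(
      rep("synthetic pathway", length(sets)), names(sets))
    list(expression = expr, gene_sets = sets, labels = labels,
         truth = do.call(rbind, truth))
  })
}
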