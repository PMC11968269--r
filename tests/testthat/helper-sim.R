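# Shared fixtures, built in code.

default_annotation <- local({
  ann <- NULL
  function() {
    if (is.null(ann)) ann <<- build_locus_annotation()
    ann
  }
})

# parameters with the power-law background switched off: the regime where
# the contact ratio has the exact closed form exp(-d * (1/l_mut - 1/l_wt))
params_no_bg <- function(...) processivity_params(background_scale = 0, ...)

closed_form_slope <- function(params) {
  -params$eta * (1 / params$lambda_mut - 1 / params$lambda_wt) / log(2)
}

# one RNA-modality fold-change table from a fresh simulation
rna_fold_change <- function(ann, params, seed, ...) {
  ex <- simulate_expression(ann, params, seed = seed, ...)
  fp <- compute_fpkm(ex)
  wt <- ex$samples$condition == "wt"
  fold_change(fp[, wt, drop = FALSE], fp[, !wt, drop = FALSE],
              modality = "RNA")
}

chip_fold_change <- function(ann, params, seed) {
  c4 <- simulate_chip_and_4c(ann, params, seed = seed)
  pk <- c4$peaks
  prom <- pk$table$kind == "promoter"
  enr <- peak_enrichment(pk$table, pk$counts, colSums(pk$counts))
  wt <- pk$samples$condition == "wt"
  fc <- fold_change(enr[prom, wt, drop = FALSE],
                    enr[prom, !wt, drop = FALSE], modality = "ChIP")
  fc$id <- pk$table$target[prom]
  fc
}

contact_fold_change <- function(ann, params, seed) {
  c4 <- simulate_chip_and_4c(ann, params, seed = seed)
  lv <- fourc_gene_levels(c4$fourc, ann)
  wt <- c4$fourc$samples$condition == "wt"
  fold_change(lv[, wt, drop = FALSE], lv[, !wt, drop = FALSE],
              modality = "contact")
}

# hand-built decoded-state object for exercising the TAD filters
fake_hmm <- function(states, posterior_of_state) {
  levels <- c("upstream", "none", "downstream")
  post <- matrix((1 - posterior_of_state) / 2, length(states), 3,
                 dimnames = list(NULL, levels))
  for (i in seq_along(states))
    post[i, states[i]] <- posterior_of_state[i]
  structure(list(posterior = post, state = states, state_levels = levels),
            class = "di_hmm")
}

# independent brute-force Poisson upper tail: direct term-by-term summation
poisson_tail_direct <- function(k, lambda, terms = 400) {
  if (k == 0) return(1)
  x <- k:(k + terms)
  sum(exp(x * log(lambda) - lambda - lgamma(x + 1)))
}
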