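# Fitting the solvent-contact parameter table (S, Omax, V per atom type)
# to dipeptide hydration free-energy data with a real-coded genetic
# algorithm. The envelope width sigma is fixed, not fitted.
#
# Because the model total is, per structure, a function of the
# type-resolved occupancy matrix only, each structure is reduced once to
# a per-atom basis matrix B with B[i, t] = sum of envelope weights from
# neighbours of type t; a fitness evaluation is then a single matrix
# product, which keeps the default GA budget (60 x 150) to seconds.

#' Genetic-algorithm configuration
#'
#' Pins down the "standard" real-coded GA completely: tournament
#' selection of size 2, uniform crossover, per-gene Gaussian mutation
#' scaled by `mutation_scale` times the gene's bound range, and elitism
#' (the best individuals are carried unchanged, which makes the
#' best-fitness trace monotone non-increasing).
#'
#' @param population_size individuals per generation (>= 2).
#' @param generations number of generations.
#' @param crossover_rate probability a selected pair is recombined.
#' @param mutation_rate per-gene mutation probability.
#' @param mutation_scale mutation step s.d. as a fraction of the gene's
#'   bound range; either a single number or a named vector with entries
#'   `S`, `Omax`, `V`. The default uses a much finer step for `S` than
#'   for the volume fields because useful solvation parameters occupy a
#'   narrow slice of their bound range while occupancy/volume genes
#'   need broad exploration (see the package vignette).
#' @param elitism number of best individuals copied unchanged.
#' @param bounds list with elements `S`, `Omax`, `V`, each a length-2
#'   numeric range. Defaults: S in [-0.5, 0.5] kcal/mol/A^3, Omax in
#'   (0, 500] A^3, V in (0, 60] A^3.
#' @param seed RNG seed; runs are bit-reproducible given the seed.
#' @return object of class `ga_config`
#' @export
ga_config <- function(population_size = 60L, generations = 150L,
                      crossover_rate = 0.9, mutation_rate = 0.15,
                      mutation_scale = c(S = 0.003, Omax = 0.03, V = 0.03),
                      elitism = 2L,
                      bounds = list(S = c(-0.5, 0.5),
                                    Omax = c(1e-3, 500),
                                    V = c(1e-3, 60)),
                      seed = 1L) {
  stopifnot(population_size >= 2, generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            all(mutation_scale > 0), elitism >= 0,
            elitism < population_size)
  if (length(mutation_scale) == 1L && is.null(names(mutation_scale)))
    mutation_scale <- c(S = unname(mutation_scale),
                        Omax = unname(mutation_scale),
                        V = unname(mutation_scale))
  if (!all(c("S", "Omax", "V") %in% names(mutation_scale)))
    stop("mutation_scale must be a scalar or name S, Omax and V",
         call. = FALSE)
  mutation_scale <- mutation_scale[c("S", "Omax", "V")]
  for (fld in c("S", "Omax", "V")) {
    b <- bounds[[fld]]
    if (is.null(b) || length(b) != 2 || b[1] >= b[2])
      stop("bounds$", fld, " must be a (lower, upper) range", call. = FALSE)
  }
  if (bounds$Omax[1] <= 0 || bounds$V[1] <= 0)
    stop("Omax and V bounds must be strictly positive", call. = FALSE)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_scale = mutation_scale,
                 elitism = as.integer(elitism),
                 bounds = bounds, seed = as.integer(seed)),
            class = "ga_config")
}

# reduce records to a stacked per-atom basis: B[i, t], atom type index,
# record index, reference energies
build_fit_basis <- function(data, sigma) {
  if (!length(data)) stop("no dipeptide records", call. = FALSE)
  structs <- lapply(data, function(r) {
    stopifnot(inherits(r, "dipeptide_record"))
    st <- r$structure
    if (anyNA(st$atoms$type)) st <- assign_atom_types(st)
    st
  })
  types <- sort(unique(unlist(lapply(structs, function(s) s$atoms$type))))
  blocks <- lapply(seq_along(structs), function(k) {
    st <- structs[[k]]
    xyz <- coords(st)
    d2 <- cross_dist2(xyz, xyz)
    G <- exp(-d2 / (2 * sigma^2))
    diag(G) <- 0
    ti <- match(st$atoms$type, types)
    # columns: total envelope weight from neighbours of each type
    B <- vapply(seq_along(types), function(t)
      rowSums(G[, ti == t, drop = FALSE]), numeric(nrow(xyz)))
    list(B = B, ti = ti, rec = rep(k, nrow(xyz)))
  })
  list(types = types,
       B = do.call(rbind, lapply(blocks, `[[`, "B")),
       ti = unlist(lapply(blocks, `[[`, "ti")),
       rec = unlist(lapply(blocks, `[[`, "rec")),
       dG_ref = vapply(data, function(r) r$dG_ref, numeric(1)),
       names = vapply(data, function(r) r$name, character(1)))
}

# predicted totals for a genome = c(S, Omax, V) blocks over basis types
basis_totals <- function(basis, S, Omax, V, clamp = TRUE) {
  O <- as.numeric(basis$B %*% V)
  Fraw <- Omax[basis$ti] - O
  Fi <- if (clamp) pmin(pmax(Fraw, 0), Omax[basis$ti]) else Fraw
  dG <- S[basis$ti] * Fi
  as.numeric(rowsum(dG, basis$rec))
}

#' RMSE of a parameter table against dipeptide reference data
#'
#' The fitting objective: root-mean-square error between the
#' solvent-contact total of each record's structure and its reference
#' hydration free energy.
#'
#' @param p a [solvation_params]
#' @param data list of [dipeptide_record]
#' @return RMSE in kcal/mol
#' @export
fitness_rmse <- function(p, data) {
  stopifnot(inherits(p, "solvation_params"))
  pred <- vapply(data, function(r) {
    st <- r$structure
    if (anyNA(st$atoms$type)) st <- assign_atom_types(st)
    hydration_energy(st, p, mode = "oracle")$total
  }, numeric(1))
  refs <- vapply(data, function(r) r$dG_ref, numeric(1))
  sqrt(mean((pred - refs)^2))
}

#' Fit solvation parameters to dipeptide data (genetic algorithm)
#'
#' Fits one (S, Omax, V) triplet per atom type present in the data by
#' minimizing [fitness_rmse()] with the real-coded GA described in
#' [ga_config()]. Sigma is fixed (default 3.5 Angstrom), taken from
#' `sigma`, not fitted.
#'
#' @param data list of [dipeptide_record] (see
#'   [gen_reference_hydration()] for the synthetic route, or
#'   [read_dipeptide_data()] for experimental TSV input).
#' @param config a [ga_config].
#' @param sigma envelope width of the fitted table, Angstrom.
#' @param init optional list of [solvation_params] injected into the
#'   initial population (e.g. a previous fit to warm-start from); with
#'   elitism, an injected optimum is never lost.
#' @return object of class `solvfit` with components `params` (the
#'   fitted [solvation_params]), `trace` (best RMSE per generation,
#'   monotone non-increasing), `rmse`, `fitted`, `reference`, `config`.
#'   Supports `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot` and `simulate`.
#' @examples
#' \donttest{
#' truth <- default_solvation_params()
#' structs <- gen_dipeptides(c("AD", "KE", "SF", "GW", "MC", "QT"))
#' data <- gen_reference_hydration(structs,
#'   synth_spec(seed = 7, true_params = truth))
#' fit <- fit_solvation_params(data, ga_config(generations = 20, seed = 7))
#' fit
#' }
#' @export
fit_solvation_params <- function(data, config = ga_config(), sigma = 3.5,
                                 init = NULL) {
  stopifnot(inherits(config, "ga_config"))
  basis <- build_fit_basis(data, sigma)
  nt <- length(basis$types)
  ng <- 3L * nt
  b <- config$bounds
  lower <- c(rep(b$S[1], nt), rep(b$Omax[1], nt), rep(b$V[1], nt))
  upper <- c(rep(b$S[2], nt), rep(b$Omax[2], nt), rep(b$V[2], nt))
  range <- upper - lower
  mut_sd <- rep(config$mutation_scale, each = nt) * range

  evaluate <- function(genome) {
    tot <- basis_totals(basis, genome[1:nt], genome[nt + 1:nt],
                        genome[2 * nt + 1:nt])
    sqrt(mean((tot - basis$dG_ref)^2))
  }

  res <- with_seed(config$seed, {
    np <- config$population_size
    pop <- matrix(stats::runif(np * ng, rep(lower, each = np),
                               rep(upper, each = np)), nrow = np)
    if (!is.null(init)) {
      for (k in seq_along(init)) {
        pk <- param_lookup(init[[k]], basis$types)
        pop[k, ] <- pmin(pmax(c(pk$S, pk$Omax, pk$V), lower), upper)
      }
    }
    fit <- apply(pop, 1, evaluate)
    trace <- numeric(config$generations)
    for (gen in seq_len(config$generations)) {
      ord <- order(fit)
      newpop <- matrix(0, np, ng)
      nelite <- config$elitism
      if (nelite > 0) newpop[seq_len(nelite), ] <-
        pop[ord[seq_len(nelite)], , drop = FALSE]
      k <- nelite
      while (k < np) {
        # tournament selection, size 2
        pick <- function() {
          ij <- sample.int(np, 2L)
          if (fit[ij[1]] <= fit[ij[2]]) ij[1] else ij[2]
        }
        p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
        if (stats::runif(1) < config$crossover_rate) {
          mask <- stats::runif(ng) < 0.5
          tmp <- p1[mask]; p1[mask] <- p2[mask]; p2[mask] <- tmp
        }
        for (child in list(p1, p2)) {
          if (k >= np) break
          mut <- stats::runif(ng) < config$mutation_rate
          if (any(mut))
            child[mut] <- child[mut] +
              stats::rnorm(sum(mut), 0, mut_sd[mut])
          child <- pmin(pmax(child, lower), upper)
          k <- k + 1L
          newpop[k, ] <- child
        }
      }
      pop <- newpop
      fit <- apply(pop, 1, evaluate)
      trace[gen] <- min(fit)
    }
    best <- pop[which.min(fit), ]
    list(best = best, trace = trace, rmse = min(fit))
  })

  params <- solvation_params(data.frame(
    type = basis$types,
    S = res$best[1:nt], Omax = res$best[nt + 1:nt],
    V = res$best[2 * nt + 1:nt], stringsAsFactors = FALSE), sigma = sigma)
  fitted_vals <- basis_totals(basis, res$best[1:nt],
                              res$best[nt + 1:nt], res$best[2 * nt + 1:nt])
  names(fitted_vals) <- basis$names
  structure(list(params = params, trace = res$trace, rmse = res$rmse,
                 fitted = fitted_vals,
                 reference = stats::setNames(basis$dG_ref, basis$names),
                 config = config, n_records = length(data),
                 call = match.call()),
            class = "solvfit")
}

#' @export
print.solvfit <- function(x, ...) {
  cat("Solvent-contact parameter fit (genetic algorithm)\n")
  cat(sprintf("  %d dipeptide records, %d atom types, sigma = %.2f A\n",
              x$n_records, nrow(x$params$types), x$params$sigma))
  cat(sprintf("  training RMSE: %.4f kcal/mol after %d generations\n",
              x$rmse, length(x$trace)))
  invisible(x)
}

#' @export
summary.solvfit <- function(object, ...) {
  res <- residuals(object)
  out <- list(rmse = object$rmse, residual_summary = summary(res),
              params = object$params, trace = object$trace,
              n_records = object$n_records)
  class(out) <- "summary.solvfit"
  out
}

#' @export
print.summary.solvfit <- function(x, ...) {
  cat("Solvent-contact parameter fit\n")
  cat(sprintf("  records: %d   training RMSE: %.4f kcal/mol\n",
              x$n_records, x$rmse))
  cat("  residuals (model - reference, kcal/mol):\n")
  print(x$residual_summary)
  cat("  fitted parameter table:\n")
  print(x$params$types, row.names = FALSE)
  invisible(x)
}

#' @export
coef.solvfit <- function(object, ...) {
  m <- as.matrix(object$params$types[, c("S", "Omax", "V")])
  rownames(m) <- object$params$types$type
  m
}

#' @export
fitted.solvfit <- function(object, ...) object$fitted

#' @export
residuals.solvfit <- function(object, ...) object$fitted - object$reference

#' Predict hydration free energies with a fitted table
#'
#' @param object a `solvfit`
#' @param newdata list of [protstruct] or of [dipeptide_record]
#' @param ... unused
#' @return named numeric vector of totals, kcal/mol
#' @export
predict.solvfit <- function(object, newdata, ...) {
  vapply(newdata, function(x) {
    st <- if (inherits(x, "dipeptide_record")) x$structure else x
    if (anyNA(st$atoms$type)) st <- assign_atom_types(st)
    hydration_energy(st, object$params, mode = "oracle")$total
  }, numeric(1))
}

#' Plot the GA convergence trace
#' @param x a `solvfit`
#' @param ... passed to [graphics::plot()]
#' @export
plot.solvfit <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "s",
                 xlab = "generation", ylab = "best RMSE (kcal/mol)",
                 main = "GA convergence", ...)
  invisible(x)
}

#' Simulate reference data from a fitted table
#'
#' Draws new reference energies for a set of structures under the
#' fitted parameters plus Gaussian noise — the parametric-bootstrap
#' companion of [gen_reference_hydration()].
#'
#' @param object a `solvfit`
#' @param nsim number of replicate data sets
#' @param seed RNG seed
#' @param structs list of [protstruct]; required
#' @param noise_sd observation-noise s.d., kcal/mol
#' @param ... unused
#' @return list of `nsim` lists of [dipeptide_record]
#' @export
simulate.solvfit <- function(object, nsim = 1, seed = 1L, structs,
                             noise_sd = 0, ...) {
  lapply(seq_len(nsim), function(k)
    gen_reference_hydration(structs,
      synth_spec(seed = seed + k - 1L, noise_sd = noise_sd,
                 true_params = object$params)))
}

#' Read dipeptide reference data from TSV
#'
#' Schema: columns `name` (two-letter dipeptide) and `dG_ref` (kcal/mol).
#' Structures are generated with [gen_dipeptides()] unless a list is
#' supplied.
#'
#' @param path TSV path
#' @param structures optional named list of [protstruct] keyed by `name`
#' @return list of [dipeptide_record]
#' @export
read_dipeptide_data <- function(path, structures = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "dG_ref") %in% names(d)))
    stop("expected columns 'name' and 'dG_ref' in ", path, call. = FALSE)
  if (is.null(structures)) structures <- gen_dipeptides(d$name)
  lapply(seq_len(nrow(d)), function(k)
    dipeptide_record(d$name[k], structures[[d$name[k]]], d$dG_ref[k]))
}
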