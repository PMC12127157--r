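# Seeded generators emulating each assay's statistical structure, so the
# whole pipeline runs and is tested without wet-lab data. Every generator
# is a pure function of its arguments and seed.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a panel of alleles with two-haplotype linkage at the
#' signature sites
#'
#' Each allele is drawn Type-I with probability `p_type_I`. Its six
#' signature-site residues are set to its type's tuple, each
#' independently flipped to the opposite tuple's residue with probability
#' `discordance_rate` (emulating the sporadic discordance seen in real
#' alignments). Each background (non-signature) position mutates away
#' from the reference with probability `other_site_mutation_rate`, drawing
#' uniformly from the residues observed at that position in the packaged
#' alignment.
#'
#' @param n_alleles Number of alleles to generate (>= 1).
#' @param p_type_I Probability an allele is generated as Type-I.
#' @param discordance_rate Per-signature-site flip probability. The
#'   packaged 29-allele alignment shows 11 discordant residues over
#'   29 x 6 sites, so 0.06 is the realistic default.
#' @param other_site_mutation_rate Per-background-site mutation
#'   probability (default 0.15, matching the packaged alignment's
#'   off-signature variant density).
#' @param signature Signature tibble, default [mica_signature()].
#' @param seed Integer seed; identical inputs give identical output.
#'
#' @return A list: `table` (a [site_table()] over the 27 packaged
#'   positions) and `truth` (tibble `allele`, `type` of generating
#'   labels).
#' @export
simulate_alleles <- function(n_alleles, p_type_I = 18 / 29,
                             discordance_rate = 0.06,
                             other_site_mutation_rate = 0.15,
                             signature = mica_signature(), seed = 1) {
  if (n_alleles < 1) stop("n_alleles must be >= 1")
  stopifnot(p_type_I >= 0, p_type_I <= 1,
            discordance_rate >= 0, discordance_rate <= 1,
            other_site_mutation_rate >= 0, other_site_mutation_rate <= 1)

  fixture <- mica_alignment()
  positions <- st_positions(fixture)
  reference <- st_reference(fixture)
  background <- setdiff(positions, signature$position)
  spectra <- polymorphic_sites(fixture)
  bg_alt <- lapply(background, function(p) {
    res <- spectra$residues[[match(p, spectra$position)]]
    setdiff(res, reference[as.character(p)])
  })
  names(bg_alt) <- background

  with_seed(seed, {
    types <- ifelse(stats::runif(n_alleles) < p_type_I, "type_I", "type_II")
    rows <- purrr::map_dfr(seq_len(n_alleles), function(i) {
      own <- if (types[i] == "type_I") signature$type_I else signature$type_II
      opp <- if (types[i] == "type_I") signature$type_II else signature$type_I
      flip <- stats::runif(length(own)) < discordance_rate
      sig_res <- ifelse(flip, opp, own)
      bg_res <- vapply(as.character(background), function(p) {
        if (stats::runif(1) < other_site_mutation_rate && length(bg_alt[[p]]) > 0) {
          sample(bg_alt[[p]], 1)
        } else {
          reference[p]
        }
      }, character(1))
      tibble::tibble(
        allele = sprintf("SIM*%04d", i),
        position = c(signature$position, background),
        residue = c(sig_res, unname(bg_res))
      )
    })
    list(
      table = site_table(dplyr::arrange(rows, .data$allele, .data$position),
                         reference, st_reference_name(fixture)),
      truth = tibble::tibble(allele = sprintf("SIM*%04d", seq_len(n_alleles)),
                             type = types)
    )
  })
}

#' Simulate a Luminex MFI panel for classified alleles
#'
#' Per classified allele and replicate, MFI is drawn from a normal
#' distribution with its type's mean and SD (negative draws truncated to
#' 0; inactive at the default parameters, whose CVs are small).
#'
#' @param calls Type calls (columns `allele`, `type`). `unclassified`
#'   alleles are skipped with a warning.
#' @param reagent Reagent whose published parameters to use (a row of
#'   [mica_mfi_params()]), default `"S001"`.
#' @param mean_I,sd_I,mean_II,sd_II Override the published parameters.
#' @param replicates Replicate wells per allele (default 3).
#' @param seed Integer seed.
#'
#' @return A long tibble: `allele`, `reagent`, `replicate`, `mfi`.
#' @export
simulate_mfi_panel <- function(calls, reagent = "S001",
                               mean_I = NULL, sd_I = NULL,
                               mean_II = NULL, sd_II = NULL,
                               replicates = 3, seed = 1) {
  stopifnot(all(c("allele", "type") %in% names(calls)), nrow(calls) > 0)
  pars <- mica_mfi_params()
  row <- pars[pars$reagent == reagent, ]
  if (nrow(row) == 1) {
    if (is.null(mean_I)) mean_I <- row$mean_I
    if (is.null(sd_I)) sd_I <- row$sd_I
    if (is.null(mean_II)) mean_II <- row$mean_II
    if (is.null(sd_II)) sd_II <- row$sd_II
  }
  if (is.null(mean_I) || is.null(sd_I) || is.null(mean_II) || is.null(sd_II)) {
    stop("unknown reagent '", reagent, "': supply mean/sd parameters explicitly")
  }
  stopifnot(sd_I >= 0, sd_II >= 0, mean_I >= 0, mean_II >= 0)

  n_skip <- sum(calls$type == "unclassified")
  if (n_skip > 0) {
    warning(n_skip, " unclassified allele(s) skipped")
  }
  keep <- calls[calls$type %in% c("type_I", "type_II"), ]

  with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(keep)), function(i) {
      mu <- if (keep$type[i] == "type_I") mean_I else mean_II
      sigma <- if (keep$type[i] == "type_I") sd_I else sd_II
      tibble::tibble(
        allele = keep$allele[i],
        reagent = reagent,
        replicate = seq_len(replicates),
        mfi = pmax(0, stats::rnorm(replicates, mu, sigma))
      )
    })
  })
}

#' Simulate 4PL dose-response measurements
#'
#' Responses are the 4PL curve of each allele's true parameters plus
#' Gaussian noise, clipped to \[0, 100\].
#'
#' @param params Data frame with columns `allele`, `bottom`, `top`,
#'   `hill`, `midpoint` (use [midpoint_for_crossing()] to target a true
#'   50% crossing).
#' @param doses Concentrations (µg/mL), default the 2-fold ladder
#'   5-160 µg/mL anchored at the 80 µg/mL coating dose.
#' @param replicates Replicates per dose (default 3).
#' @param noise_sd Gaussian noise SD in percentage points (default 3).
#' @param seed Integer seed.
#'
#' @return A long tibble: `allele`, `dose`, `replicate`, `response`.
#' @export
simulate_dose_response <- function(params, doses = 5 * 2^(0:5),
                                   replicates = 3, noise_sd = 3, seed = 1) {
  stopifnot(all(c("allele", "bottom", "top", "hill", "midpoint") %in% names(params)),
            all(doses > 0), !is.unsorted(doses, strictly = TRUE), noise_sd >= 0)
  with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(params)), function(i) {
      p <- params[i, ]
      grid <- tidyr::expand_grid(dose = doses, replicate = seq_len(replicates))
      y <- logistic4(grid$dose, p$bottom, p$top, p$hill, p$midpoint)
      y <- y + stats::rnorm(nrow(grid), 0, noise_sd)
      tibble::tibble(allele = p$allele, dose = grid$dose,
                     replicate = grid$replicate,
                     response = pmin(100, pmax(0, y)))
    })
  })
}

#' Simulate flow-count killing assays
#'
#' Dead-cell counts are binomial draws at each (target, ratio) true rate.
#'
#' @param rates Data frame with columns `target`, `ratio`, `rate`
#'   (per-cell killing probability in \[0, 1\]).
#' @param n_total CFSE+ target events per well (default 5000).
#' @param replicates Replicate wells (default 3).
#' @param seed Integer seed.
#'
#' @return A long tibble: `target`, `ratio`, `replicate`, `n_total`,
#'   `n_dead`.
#' @export
simulate_killing <- function(rates, n_total = 5000, replicates = 3, seed = 1) {
  stopifnot(all(c("target", "ratio", "rate") %in% names(rates)),
            all(rates$rate >= 0), all(rates$rate <= 1), n_total >= 1)
  with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(rates)), function(i) {
      tibble::tibble(
        target = rates$target[i],
        ratio = rates$ratio[i],
        replicate = seq_len(replicates),
        n_total = n_total,
        n_dead = stats::rbinom(replicates, n_total, rates$rate[i])
      )
    })
  })
}
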