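# Approximate human proteome amino-acid background frequencies.
aa_background <- function() {
  f <- c(A = 7.0, R = 5.6, N = 3.6, D = 4.7, C = 2.3, Q = 4.8, E = 7.1,
         G = 6.6, H = 2.6, I = 4.3, L = 10.0, K = 5.7, M = 2.1, F = 3.7,
         P = 6.3, S = 8.3, T = 5.4, W = 1.2, Y = 2.7, V = 6.0)
  f / sum(f)
}

#' Generate a synthetic phosphoproteome world with known ground truth
#'
#' Builds a set of S/T kinases with sequence motifs, substrate
#' phosphosites whose 15-mer windows are drawn from their regulating
#' kinase's motif, background phosphosites with no regulator, and the
#' matching gold interactome table in the standard record dialect — so
#' the full pipeline (labels, similarity filter, evaluation) runs with no
#' external data.
#'
#' Each kinase motif fixes a few specificity positions where one residue
#' is strongly preferred; each substrate window adheres to the motif
#' strongly with probability `p_strong` and weakly otherwise, giving
#' same-kinase window pairs a modestly right-shifted similarity
#' distribution over random pairs, as seen interactome-wide in real data.
#'
#' @param n_kinases number of kinases (default 8).
#' @param n_substrates_per_kinase substrates regulated by each kinase
#'   (default 10).
#' @param n_background unregulated background substrates; default 30% of
#'   the regulated count.
#' @param n_specific motif specificity positions per kinase (default 5).
#' @param p_strong probability a substrate adheres strongly to its
#'   kinase's motif (default 0.5).
#' @param q_strong,q_weak preferred-residue probability at specificity
#'   positions for strong/weak adherence (defaults 0.95, 0.3).
#' @param gain_range substrate response gain interval (default
#'   `c(0.5, 2)`).
#' @param noise_sd measurement noise standard deviation on the log2 scale
#'   (default 1.5).
#' @param seed integer seed.
#' @return A `synthetic_world`: tibbles `kinases`, `substrates` (with
#'   windows and regulator assignment), `sites` (all measured sites
#'   including kinase phosphosites), `interactome` (gold records),
#'   `kinase_classes`, plus `windows` (named vector) and the generator
#'   parameters.
#' @export
generate_world <- function(n_kinases = 8, n_substrates_per_kinase = 10,
                           n_background = NULL, n_specific = 5,
                           p_strong = 0.5, q_strong = 0.95, q_weak = 0.3,
                           gain_range = c(0.5, 2), noise_sd = 1.5, seed = 1) {
  stopifnot(n_kinases >= 1, n_substrates_per_kinase >= 1)
  n_background <- n_background %||%
    round(0.3 * n_kinases * n_substrates_per_kinase)
  set.seed(seed)
  aa <- aa_background()
  aas <- names(aa)
  draw_window <- function(probs_list, center) {
    paste0(paste(vapply(1:7, function(p) sample(aas, 1, prob = probs_list[[p]]),
                        ""), collapse = ""),
           center,
           paste(vapply(9:15, function(p) sample(aas, 1,
                                                 prob = probs_list[[p]]), ""),
                 collapse = ""))
  }
  bg_probs <- rep(list(aa), 15)

  kinases <- tibble::tibble(
    kinase = sprintf("KIN%02d", seq_len(n_kinases)),
    center = sample(c("S", "T"), n_kinases, TRUE))
  motifs <- lapply(seq_len(n_kinases), function(k) {
    spec_pos <- sample(setdiff(1:15, 8), n_specific)
    pref <- sample(aas, n_specific, prob = aa)
    list(spec_pos = spec_pos, pref = pref)
  })

  motif_probs <- function(k, strong) {
    q <- if (strong) q_strong else q_weak
    probs <- bg_probs
    m <- motifs[[k]]
    for (s in seq_along(m$spec_pos)) {
      p <- aa * (1 - q)
      p[m$pref[s]] <- p[m$pref[s]] + q
      probs[[m$spec_pos[s]]] <- p
    }
    probs
  }

  n_sub <- n_kinases * n_substrates_per_kinase
  sub_kinase <- rep(seq_len(n_kinases), each = n_substrates_per_kinase)
  strong <- runif(n_sub) < p_strong
  sub_center <- kinases$center[sub_kinase]
  sub_windows <- vapply(seq_len(n_sub), function(i) {
    draw_window(motif_probs(sub_kinase[i], strong[i]), sub_center[i])
  }, "")
  bg_center <- sample(c("S", "T"), n_background, TRUE)
  bg_windows <- vapply(seq_len(max(n_background, 0)), function(i) {
    draw_window(bg_probs, bg_center[i])
  }, "")

  positions <- sample(10:600, n_sub + n_background + n_kinases, TRUE)
  substrates <- tibble::tibble(
    accession = sprintf("SUB%03d", seq_len(n_sub + n_background)),
    residue = c(sub_center, bg_center),
    position = positions[seq_len(n_sub + n_background)],
    window = c(sub_windows, bg_windows),
    kinase = c(kinases$kinase[sub_kinase], rep(NA, n_background)),
    gain = c(runif(n_sub, gain_range[1], gain_range[2]),
             rep(NA, n_background)))
  substrates$site <- site_id(substrates$accession, substrates$residue,
                             substrates$position)

  # each kinase also carries a measured phosphosite of its own, with a
  # background window (a kinase's own site need not match its motif)
  kin_center <- sample(c("S", "T"), n_kinases, TRUE)
  kin_sites <- tibble::tibble(
    accession = kinases$kinase,
    residue = kin_center,
    position = positions[n_sub + n_background + seq_len(n_kinases)],
    window = vapply(seq_len(n_kinases),
                    function(i) draw_window(bg_probs, kin_center[i]), ""),
    kinase = NA_character_, gain = NA_real_)
  kin_sites$site <- site_id(kin_sites$accession, kin_sites$residue,
                            kin_sites$position)

  sites <- dplyr::bind_rows(substrates, kin_sites)
  regulated <- substrates[!is.na(substrates$kinase), , drop = FALSE]
  interactome <- tibble::tibble(
    kinase = regulated$kinase, substrate = regulated$accession,
    residue = regulated$residue, position = regulated$position,
    source = "database", probability = NA_real_,
    site = regulated$site)

  structure(list(
    kinases = kinases, substrates = substrates, sites = sites,
    interactome = interactome,
    kinase_classes = tibble::tibble(kinase = kinases$kinase, class = "ST"),
    windows = stats::setNames(sites$window, sites$site),
    noise_sd = noise_sd, seed = seed,
    params = list(n_kinases = n_kinases,
                  n_substrates_per_kinase = n_substrates_per_kinase,
                  n_background = n_background, n_specific = n_specific,
                  p_strong = p_strong, q_strong = q_strong, q_weak = q_weak,
                  gain_range = gain_range)),
    class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> ", nrow(x$kinases), " kinases, ",
      nrow(x$substrates), " substrates (",
      sum(is.na(x$substrates$kinase)), " background), ",
      nrow(x$interactome), " gold interactions\n", sep = "")
  invisible(x)
}

# Random smooth activity curve: sum of two logistic ramps, standardized
# across the sampled timepoints.
activity_curve <- function(t) {
  a <- rowSums(vapply(1:2, function(l) {
    b <- runif(1, 0.5, 2) * sample(c(-1, 1), 1)
    m <- runif(1, min(t), max(t))
    s <- runif(1, 0.5, 0.2 * diff(range(t)) + 0.5)
    b / (1 + exp(-(t - m) / s))
  }, numeric(length(t))))
  if (sd(a) < 1e-8) a else (a - mean(a)) / sd(a)
}

#' Simulate a time-series dataset from a synthetic world
#'
#' Kinase activities follow random smooth curves; each substrate's log2
#' fold change tracks its regulating kinase's activity scaled by the
#' substrate gain, plus Gaussian noise; background substrates are pure
#' noise; each kinase's own phosphosite tracks its activity so
#' kinase-substrate candidate rows exist in the matrix.
#'
#' @param world a `synthetic_world`.
#' @param n_timepoints number of sampled timepoints (default 8; real
#'   dynamic designs span roughly four to ten).
#' @param seed integer seed.
#' @return A `phospho_dataset` (sites x timepoints) whose `truth` is the
#'   world's gold interactome.
#' @export
generate_timeseries <- function(world, n_timepoints = 8, seed = 1) {
  stopifnot(inherits(world, "synthetic_world"))
  set.seed(seed)
  t <- seq_len(n_timepoints)
  act <- vapply(seq_len(nrow(world$kinases)), function(k) activity_curve(t),
                numeric(n_timepoints))
  colnames(act) <- world$kinases$kinase
  sites <- world$sites
  X <- matrix(rnorm(nrow(sites) * n_timepoints, 0, world$noise_sd),
              nrow(sites), n_timepoints,
              dimnames = list(sites$site, paste0("t", t)))
  reg <- !is.na(sites$kinase)
  X[reg, ] <- X[reg, ] +
    sites$gain[reg] * t(act)[sites$kinase[reg], , drop = FALSE]
  is_kin <- sites$accession %in% world$kinases$kinase
  X[is_kin, ] <- X[is_kin, ] + t(act)[sites$accession[is_kin], , drop = FALSE]
  phospho_dataset(X,
                  sample_info = tibble::tibble(sample = colnames(X),
                                               timepoint = t),
                  truth = world$interactome, type = "timeseries")
}

#' Simulate a perturbation panel from a synthetic world
#'
#' Each condition inhibits a random kinase subset; substrates of an
#' inhibited kinase shift down by their gain, plus noise. A synthetic
#' per-site per-condition p-value table (from the standardized effect
#' size) is returned so the perturbation regulation filter is
#' exercisable.
#'
#' @param world a `synthetic_world`.
#' @param n_conditions number of perturbation conditions (default 48, the
#'   scale of published kinase-inhibitor panels).
#' @param inhibit_prob per-condition probability a given kinase is
#'   inhibited (default 0.25).
#' @param seed integer seed.
#' @return List: `data` (a `phospho_dataset` of type `"perturbation"`),
#'   `pvalues` (matrix), `inhibited` (kinases x conditions logical).
#' @export
generate_perturbation <- function(world, n_conditions = 48,
                                  inhibit_prob = 0.25, seed = 1) {
  stopifnot(inherits(world, "synthetic_world"), n_conditions >= 2)
  set.seed(seed)
  nk <- nrow(world$kinases)
  inhibited <- matrix(runif(nk * n_conditions) < inhibit_prob, nk,
                      n_conditions,
                      dimnames = list(world$kinases$kinase,
                                      sprintf("cond%02d", 1:n_conditions)))
  sites <- world$sites
  X <- matrix(rnorm(nrow(sites) * n_conditions, 0, world$noise_sd),
              nrow(sites), n_conditions,
              dimnames = list(sites$site, colnames(inhibited)))
  reg <- which(!is.na(sites$kinase))
  X[reg, ] <- X[reg, ] -
    sites$gain[reg] * inhibited[sites$kinase[reg], , drop = FALSE]
  is_kin <- sites$accession %in% world$kinases$kinase
  X[is_kin, ] <- X[is_kin, ] - 1 * inhibited[sites$accession[is_kin], ,
                                             drop = FALSE]
  p <- 2 * stats::pnorm(-abs(X) / world$noise_sd)
  ds <- phospho_dataset(X,
                        sample_info = tibble::tibble(
                          sample = colnames(X),
                          condition = colnames(X)),
                        truth = world$interactome, type = "perturbation")
  list(data = ds, pvalues = p, inhibited = inhibited)
}
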