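# Latent attribution ----------------------------------------------------------
#
# "Contribution rates" quantify how much each input item drives each latent
# coordinate: the absolute value of the mean, over a patient subset, of the
# first-order partial derivative of the coordinate with respect to the
# (scaled) input item. Derivatives are analytic, obtained by chaining the
# encoder's layer Jacobians. Reported columns follow the feature-vector
# convention X = -x, Y = -y, Z = +z; the sign flip leaves the absolute
# rates unchanged but matters for the retained signed means, which state
# the direction of increase of an item along a feature vector.

#' Feature-vector sign convention
#'
#' The raw latent axes x and y are reported with their signs flipped
#' (feature vectors X = -x and Y = -y); Z keeps the sign of z. Applying the
#' convention twice restores the raw axes.
#'
#' @return Named numeric vector of signs for (x, y, z).
#' @export
axis_convention <- function() c(x = -1, y = -1, z = 1)

#' Analytic Jacobian of the encoder at one input
#'
#' Entry (a, i) is the partial derivative of latent coordinate a with
#' respect to input item i, evaluated at the given (scaled) input vector
#' and computed exactly by backpropagating identity seeds through the
#' encoder layers.
#'
#' @param model Trained `sle_autoencoder`.
#' @param x Numeric input vector of length equal to the encoder input width.
#' @return Numeric matrix, bottleneck x items; rows named x/y/z for a
#'   3-dimensional bottleneck, columns named by item when `x` is named.
#' @export
encoder_jacobian <- function(model, x) {
  d_in <- model$config$layer_sizes_encoder[1]
  if (length(x) != d_in) {
    abort(sprintf("input has length %d but the encoder expects %d", length(x), d_in))
  }
  J <- encoder_jacobians(model, matrix(as.numeric(x), nrow = 1))[[1]]
  d_lat <- nrow(J)
  if (d_lat == 3) rownames(J) <- c("x", "y", "z")
  if (!is.null(names(x))) colnames(J) <- names(x)
  J
}

# Jacobians for every row of X in one shared forward pass.
# Returns a list of (bottleneck x items) matrices.
encoder_jacobians <- function(model, X) {
  nE <- model$n_encoder_layers
  fwd <- ae_forward(model, X, n_layers = nE)
  d_lat <- ncol(fwd$A[[nE + 1L]])
  # per-layer activation derivatives, n x width
  D <- purrr::map(seq_len(nE), function(l) {
    activation_grad(model$activations[l])(fwd$Z[[l]], fwd$A[[l + 1L]])
  })
  purrr::map(seq_len(nrow(X)), function(i) {
    J <- diag(1, d_lat)
    for (l in rev(seq_len(nE))) {
      J <- sweep(J, 2, D[[l]][i, ], `*`) %*% t(model$weights[[l]]$W)
    }
    J
  })
}

#' Contribution rates of input items for each feature vector
#'
#' For each item and latent axis, the per-patient encoder partial
#' derivatives are averaged over the given subset and the absolute value of
#' that mean is the contribution rate (absolute of the mean, not mean of
#' absolutes: equal-magnitude opposite-sign derivatives cancel). The
#' pipeline default subset is the patients with kidney involvement. Signed
#' means (after the X/Y/Z sign convention) are retained in the
#' `signed_means` attribute for direction-of-increase reports.
#'
#' @param model Trained `sle_autoencoder`.
#' @param features Feature matrix or `cohort_matrix`.
#' @param subset Logical or integer patient mask; default all rows. For a
#'   `cohort_matrix`, `subset = "kidney"` selects patients with kidney
#'   involvement.
#' @return A `contribution_table` tibble: `item_id`, `X`, `Y`, `Z` (rates,
#'   all non-negative), with attributes `signed_means` (tibble of signed
#'   mean derivatives per feature vector) and `subset_size`.
#' @export
contribution_rates <- function(model, features, subset = NULL) {
  cm <- NULL
  if (inherits(features, "cohort_matrix")) {
    cm <- features
    features <- cm$features
  }
  if (is.character(subset)) {
    if (!identical(subset, "kidney") || is.null(cm)) {
      abort('character subset must be "kidney" and requires a cohort_matrix')
    }
    subset <- cm$kidney_involvement == 1L
  }
  subset <- subset %||% rep(TRUE, nrow(features))
  X <- features[subset, , drop = FALSE]
  if (nrow(X) == 0) abort("contribution_rates needs a non-empty patient subset")
  Js <- encoder_jacobians(model, X)
  mean_J <- Reduce(`+`, Js) / length(Js)  # bottleneck x items
  signs <- axis_convention()
  item_ids <- colnames(features) %||% sprintf("item_%02d", seq_len(ncol(features)))
  signed <- tibble::tibble(
    item_id = item_ids,
    X = signs[["x"]] * mean_J[1, ],
    Y = signs[["y"]] * mean_J[2, ],
    Z = signs[["z"]] * mean_J[3, ]
  )
  rates <- dplyr::mutate(signed, X = abs(.data$X), Y = abs(.data$Y), Z = abs(.data$Z))
  class(rates) <- c("contribution_table", class(rates))
  attr(rates, "signed_means") <- signed
  attr(rates, "subset_size") <- nrow(X)
  rates
}

#' Top contributing items per feature vector
#'
#' @param table A `contribution_table`.
#' @param k Number of items to report per feature vector (the headline
#'   report uses 6). Values above the item count are truncated with a
#'   warning. Ties are broken by item order in the table, which follows the
#'   schema, so rankings are deterministic.
#' @return Tibble: `feature_vector`, `rank`, `item_id`, `rate`.
#' @export
top_contributors <- function(table, k = 6) {
  if (k < 1) abort("k must be >= 1")
  n <- nrow(table)
  if (k > n) {
    warn(sprintf("k = %d exceeds the %d items; truncated", k, n))
    k <- n
  }
  purrr::map_dfr(c("X", "Y", "Z"), function(axis) {
    ord <- order(-table[[axis]], seq_len(n))
    tibble::tibble(
      feature_vector = axis,
      rank = seq_len(k),
      item_id = table$item_id[ord[seq_len(k)]],
      rate = table[[axis]][ord[seq_len(k)]]
    )
  })
}

#' Identify the titer-gradient axes of the latent space
#'
#' The association scans operate on a two-dimensional working plane whose
#' first axis carries the anti-dsDNA titer gradient and whose second
#' carries the antinuclear-antibody gradient. Which raw latent axes those
#' are depends on the fit (the network is symmetric under axis
#' permutation), so the plane is chosen from the data, the same way the
#' original analysis verified the titer gradients on its plane before
#' fixing it: the dsDNA axis is the latent axis most correlated (in
#' absolute value) with the log2 anti-dsDNA titer, and the ANA axis is the
#' most ANA-correlated of the remaining two.
#'
#' @param embedding A `latent_embedding`.
#' @param cohort Curated cohort tibble or `cohort_matrix`, row-aligned,
#'   providing raw `dsdna_titer` and `ana_titer`.
#' @return A list with `x_axis` and `z_axis` (names among "x", "y", "z"),
#'   the correlation matrix `cors`, and `plane`, the embedding with the
#'   selected axes relabelled as `x` and `z` (ready for the scan
#'   functions).
#' @export
select_feature_plane <- function(embedding, cohort) {
  if (inherits(cohort, "cohort_matrix")) cohort <- cohort$cohort
  stopifnot(nrow(cohort) == nrow(embedding))
  lat <- as.matrix(embedding[, c("x", "y", "z")])
  cors <- cbind(
    dsdna = as.vector(stats::cor(lat, log2(pmax(cohort$dsdna_titer, 1)))),
    ana = as.vector(stats::cor(lat, log2(pmax(cohort$ana_titer, 1))))
  )
  rownames(cors) <- c("x", "y", "z")
  x_axis <- rownames(cors)[which.max(abs(cors[, "dsdna"]))]
  rest <- setdiff(rownames(cors), x_axis)
  z_axis <- rest[which.max(abs(cors[rest, "ana"]))]
  plane <- tibble::tibble(
    patient_id = embedding$patient_id,
    x = embedding[[x_axis]],
    y = embedding[[setdiff(c("x", "y", "z"), c(x_axis, z_axis))]],
    z = embedding[[z_axis]]
  )
  class(plane) <- c("latent_embedding", class(plane))
  list(x_axis = x_axis, z_axis = z_axis, cors = cors, plane = plane)
}

#' Exclude patients with extremely high anti-dsDNA titers
#'
#' Patients with an anti-dsDNA antibody titer at or above the cutoff
#' (default 500, which on the doubling-dilution ladder first bites at the
#' 640 rung) sit apart on the y-axis and are removed before any analysis on
#' the two-dimensional (x, z) feature plane.
#'
#' @param embedding A `latent_embedding` tibble.
#' @param cohort Curated cohort tibble (or `cohort_matrix`) providing the
#'   raw `dsdna_titer` values, row-aligned with the embedding.
#' @param cutoff Titer cutoff; a titer `>= cutoff` is excluded.
#' @return A list with `embedding` (retained rows), `excluded` (logical
#'   mask over the input rows) and `n_excluded`.
#' @export
exclude_high_dsdna <- function(embedding, cohort, cutoff = 500) {
  if (inherits(cohort, "cohort_matrix")) cohort <- cohort$cohort
  if (!"dsdna_titer" %in% names(cohort)) abort("cohort lacks the dsdna_titer item")
  if (nrow(cohort) != nrow(embedding)) {
    abort("embedding and cohort must be row-aligned")
  }
  titer <- cohort$dsdna_titer
  excluded <- !is.na(titer) & titer >= cutoff
  list(
    embedding = embedding[!excluded, , drop = FALSE],
    excluded = excluded,
    n_excluded = sum(excluded)
  )
}
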