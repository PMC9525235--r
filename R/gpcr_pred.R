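# Peptide-GPCR pair prediction: z-scale descriptors for peptides and
# receptor transmembrane segments, linearized outer-product features,
# shuffle-generated negatives, a two-class SVM with Platt-calibrated
# [0,1] scores, 7-TM receptor filtering, representative-peptide selection
# and the receptor-to-peptide assignment rules.

#' Five-component z-scale descriptors of the 20 amino acids
#'
#' The extended z-scales of Sandberg et al. (1998, J. Med. Chem. 41:2481),
#' five principal-property components per residue capturing
#' lipophilicity, steric bulk, polarity and electronic effects.
#'
#' @return A 20 x 5 numeric matrix, rows named by residue letter.
#' @export
z_scales <- function() {
  m <- matrix(c(
     0.24, -2.32,  0.60, -0.14,  1.30,  # A
     0.84, -1.67,  3.71,  0.18, -2.65,  # C
     3.98,  0.93,  1.93, -2.46,  0.75,  # D
     3.11,  0.26, -0.11, -3.04, -0.25,  # E
    -4.22,  1.94,  1.06,  0.54, -0.62,  # F
     2.05, -4.06,  0.36, -0.82, -0.38,  # G
     2.47,  1.95,  0.26,  3.90,  0.09,  # H
    -3.89, -1.73, -1.71, -0.84,  0.26,  # I
     2.29,  0.89, -2.49,  1.49,  0.31,  # K
    -4.28, -1.30, -1.49, -0.72,  0.84,  # L
    -2.85, -0.22,  0.47,  1.94, -0.98,  # M
     3.05,  1.62,  1.04, -1.15,  1.61,  # N
    -1.66,  0.27,  1.84,  0.70,  2.00,  # P
     1.75,  0.50, -1.44, -1.34,  0.66,  # Q
     3.52,  2.50, -3.50,  1.99, -0.17,  # R
     2.39, -1.07,  1.15, -1.39,  0.67,  # S
     0.75, -2.18, -1.12, -1.46, -0.40,  # T
    -2.59, -2.64, -1.54, -0.85, -0.02,  # V
    -4.36,  3.94,  0.59,  3.44, -1.59,  # W
    -2.54,  2.44,  0.43,  0.04, -1.47   # Y
  ), ncol = 5, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                  paste0("z", 1:5)))
  m
}

.zrows <- function(chars, zm) {
  bad <- setdiff(chars, rownames(zm))
  if (length(bad)) {
    stop("non-canonical residue(s): ", paste(unique(bad), collapse = ", "))
  }
  zm[chars, , drop = FALSE]
}

#' Peptide descriptor vector
#'
#' Deterministic 37-dimensional descriptor: the five z-scale means over the
#' whole sequence, the position-specific z-scales of the three N-terminal
#' and three C-terminal residues, the peptide length, and a C-terminal
#' amidation indicator.
#'
#' @param p A [peptidoform()], or a character sequence (then `amidated`
#'   supplies the flag).
#' @param amidated Amidation flag when `p` is a bare sequence.
#' @return Named numeric vector of length 37.
#' @export
peptide_descriptor <- function(p, amidated = FALSE) {
  if (inherits(p, "peptidoform")) {
    seq <- p$sequence
    amidated <- p$c_amidated
  } else {
    seq <- p
  }
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) < 3L) stop("peptide descriptor requires length >= 3")
  zm <- z_scales()
  zs <- .zrows(chars, zm)
  n <- length(chars)
  v <- c(colMeans(zs),
         as.vector(t(zs[1:3, , drop = FALSE])),
         as.vector(t(zs[(n - 2):n, , drop = FALSE])),
         n,
         as.numeric(isTRUE(amidated)))
  names(v) <- c(paste0("mean_z", 1:5),
                paste0("nt", rep(1:3, each = 5), "_z", 1:5),
                paste0("ct", rep(1:3, each = 5), "_z", 1:5),
                "length", "amidated")
  v
}

#' Construct a receptor model
#'
#' @param receptor_id Identifier.
#' @param sequence Receptor amino-acid sequence.
#' @param tm_segments Data frame with 0-based half-open `start`, `end`
#'   columns, one row per transmembrane segment, non-overlapping and
#'   ascending. A receptor is "full-length" iff it has exactly 7 segments.
#' @return An object of class `receptor_model`.
#' @export
receptor_model <- function(receptor_id, sequence, tm_segments) {
  tm_segments <- as.data.frame(tm_segments)
  stopifnot(all(c("start", "end") %in% names(tm_segments)))
  tm_segments <- tm_segments[order(tm_segments$start), , drop = FALSE]
  stopifnot(all(tm_segments$end <= nchar(sequence)),
            all(tm_segments$start < tm_segments$end))
  if (nrow(tm_segments) > 1L) {
    stopifnot(all(tm_segments$start[-1] >= tm_segments$end[-nrow(tm_segments)]))
  }
  structure(list(receptor_id = receptor_id, sequence = sequence,
                 tm_segments = tm_segments),
            class = "receptor_model")
}

#' Is a receptor full-length (7 TM segments)?
#' @param r A [receptor_model()].
#' @return Logical.
#' @export
is_full_length <- function(r) nrow(r$tm_segments) == 7L

#' Receptor TM z-scale descriptor
#'
#' Per-segment five z-scale means over the seven transmembrane segments,
#' concatenated in segment order (35 dimensions). Refuses receptors that do
#' not carry exactly 7 segments; callers must pre-filter with
#' [filter_seven_tm()].
#'
#' @param r A [receptor_model()].
#' @return Named numeric vector of length 35.
#' @export
receptor_descriptor <- function(r) {
  stopifnot(inherits(r, "receptor_model"))
  if (!is_full_length(r)) {
    stop("receptor ", r$receptor_id, " has ", nrow(r$tm_segments),
         " TM segments; descriptor requires exactly 7")
  }
  zm <- z_scales()
  v <- unlist(lapply(seq_len(7L), function(k) {
    s <- r$tm_segments$start[k]
    e <- r$tm_segments$end[k]
    chars <- strsplit(substr(r$sequence, s + 1L, e), "")[[1]]
    colMeans(.zrows(chars, zm))
  }))
  names(v) <- paste0("tm", rep(1:7, each = 5), "_z", 1:5)
  v
}

#' Linearized outer product of two descriptor vectors
#'
#' Row-major flattening of the outer product: `features[(i-1)*q + j] =
#' pep_vec[i] * rec_vec[j]`.
#'
#' @param pep_vec,rec_vec Non-empty numeric vectors (lengths p and q).
#' @return Numeric vector of length `p * q`.
#' @export
linearized_outer_product <- function(pep_vec, rec_vec) {
  stopifnot(length(pep_vec) > 0, length(rec_vec) > 0)
  as.vector(t(outer(pep_vec, rec_vec)))
}

#' Keep only full-length (7-TM) receptors
#'
#' @param receptors List of [receptor_model()] objects.
#' @return The sublist with exactly 7 TM segments.
#' @export
filter_seven_tm <- function(receptors) {
  Filter(is_full_length, receptors)
}

#' Generate shuffle negatives for CPI training
#'
#' Non-interaction pairs are random peptide x receptor recombinations of
#' the identities occurring among the positives, excluding any pair present
#' among the positives. Sampling is reproducible under `seed`.
#'
#' @param positives Data frame with `peptide_id` and `receptor_id` columns.
#' @param ratio Negatives per positive (default 1).
#' @param seed Integer seed.
#' @return Data frame of negative pairs with a `label` column set to
#'   `"non_interact"`.
#' @export
generate_negatives <- function(positives, ratio = 1, seed = 1L) {
  peps <- unique(positives$peptide_id)
  recs <- unique(positives$receptor_id)
  stopifnot(length(peps) >= 2L, length(recs) >= 2L)
  n_wanted <- round(ratio * nrow(positives))
  grid <- expand.grid(peptide_id = peps, receptor_id = recs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pos_key <- paste(positives$peptide_id, positives$receptor_id, sep = "\r")
  grid <- grid[!(paste(grid$peptide_id, grid$receptor_id, sep = "\r") %in% pos_key), ,
               drop = FALSE]
  if (nrow(grid) < n_wanted) {
    stop("requested ", n_wanted, " negatives but only ", nrow(grid),
         " non-positive pairs exist")
  }
  idx <- with_seed(seed, sample(nrow(grid), n_wanted))
  out <- grid[sort(idx), , drop = FALSE]
  out$label <- "non_interact"
  rownames(out) <- NULL
  out
}

#' Train the peptide-GPCR interaction model
#'
#' Two-class support vector machine on linearized outer-product features,
#' with Platt-calibrated scores: the SVM decision values on the training
#' set are mapped through a binomial GLM sigmoid so that `score()` returns
#' values in \[0, 1\] (0 = no interaction, 1 = interaction). Training is
#' deterministic given the data, the hyperparameters and `seed`.
#'
#' The default kernel is linear: interaction rules that are bilinear in the
#' peptide and receptor descriptors are exactly linear in the outer-product
#' feature space, and the max-margin linear decision value is then a
#' monotone surrogate of the underlying interaction strength, which the
#' downstream ranking-based assignment requires. A radial kernel is
#' available via `kernel`.
#'
#' @param features Numeric matrix, one row per pair.
#' @param labels Factor or character with exactly the two classes
#'   `interact` / `non_interact` (both must be present).
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param cost,gamma SVM hyperparameters (`gamma` only for the radial
#'   kernel; default `1/ncol(features)`).
#' @param tune If `TRUE`, a small grid (`cost` in 1, 10; for radial kernels
#'   also `gamma` in 1x and 0.1x the default) is searched by fixed-seed
#'   3-fold cross-validation before the final fit.
#' @param seed Integer seed controlling the cross-validation folds.
#' @return An object of class `cpi_model` with a `$score(newx)` closure.
#' @export
train_cpi_model <- function(features, labels, kernel = "linear",
                            cost = 1, gamma = NULL, tune = FALSE, seed = 1L) {
  labels <- factor(as.character(labels), levels = c("interact", "non_interact"))
  if (any(is.na(labels))) stop("labels must be 'interact' or 'non_interact'")
  if (nlevels(droplevels(labels)) < 2L) {
    stop("training requires both classes to be present")
  }
  features <- as.matrix(features)
  if (is.null(gamma)) gamma <- 1 / ncol(features)

  fit_one <- function(x, y, cost, gamma) {
    e1071::svm(x, y, kernel = kernel, cost = cost, gamma = gamma,
               scale = FALSE, probability = FALSE)
  }
  # constant-feature columns break e1071's internal scaling; scale manually
  mu <- colMeans(features)
  sd <- apply(features, 2, stats::sd)
  sd[sd == 0] <- 1
  xs <- sweep(sweep(features, 2, mu), 2, sd, "/")

  if (tune) {
    grid <- if (kernel == "radial") {
      expand.grid(cost = c(1, 10), gamma = c(gamma, gamma / 10))
    } else {
      expand.grid(cost = c(1, 10), gamma = gamma)
    }
    folds <- with_seed(seed, sample(rep_len(1:3, nrow(xs))))
    acc <- vapply(seq_len(nrow(grid)), function(g) {
      mean(vapply(1:3, function(f) {
        fit <- fit_one(xs[folds != f, , drop = FALSE], labels[folds != f],
                       grid$cost[g], grid$gamma[g])
        mean(predict(fit, xs[folds == f, , drop = FALSE]) == labels[folds == f])
      }, numeric(1)))
    }, numeric(1))
    best <- which.max(acc)
    cost <- grid$cost[best]
    gamma <- grid$gamma[best]
  }

  fit <- fit_one(xs, labels, cost, gamma)
  dv <- as.numeric(attr(predict(fit, xs, decision.values = TRUE),
                        "decision.values"))
  # orient decision values so larger = interact
  orient <- if (colnames(attr(predict(fit, xs[1, , drop = FALSE],
                                      decision.values = TRUE),
                              "decision.values")) == "interact/non_interact") 1 else -1
  dv <- orient * dv
  y01 <- as.numeric(labels == "interact")
  ab <- .platt_fit(dv, y01)
  a <- ab[1]
  b <- ab[2]

  model <- structure(list(fit = fit, orient = orient, platt_a = a, platt_b = b,
                          center = mu, scale = sd, kernel = kernel,
                          cost = cost, gamma = gamma),
                     class = "cpi_model")
  model$score <- function(newx) score_pairs(model, newx)
  model
}

# Platt (1999) sigmoid calibration of decision values: cross-entropy fit of
# p = plogis(a*dv + b) against regularized targets t+ = (N+ + 1)/(N+ + 2),
# t- = 1/(N- + 2). The soft targets keep the optimum finite on separable
# data, so calibrated scores remain strictly monotone in the decision value
# (no 0/1 saturation, no ties).
.platt_fit <- function(dv, y01) {
  np <- sum(y01 == 1)
  nn <- sum(y01 == 0)
  t <- ifelse(y01 == 1, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    z <- par[1] * dv + par[2]
    # stable cross-entropy: t*log(1+e^-z) + (1-t)*log(1+e^z)
    sum(t * log1p(exp(-abs(z))) + (1 - t) * log1p(exp(-abs(z))) +
          ifelse(z > 0, (1 - t) * z, -t * z))
  }
  grad <- function(par) {
    p <- stats::plogis(par[1] * dv + par[2])
    c(sum((p - t) * dv), sum(p - t))
  }
  fit <- stats::optim(c(1, 0), nll, grad, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  fit$par
}

#' Score feature rows with a trained CPI model
#'
#' @param model A `cpi_model` from [train_cpi_model()].
#' @param newx Numeric matrix of outer-product features.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
score_pairs <- function(model, newx) {
  newx <- as.matrix(newx)
  xs <- sweep(sweep(newx, 2, model$center), 2, model$scale, "/")
  dv <- model$orient * as.numeric(attr(predict(model$fit, xs,
                                               decision.values = TRUE),
                                       "decision.values"))
  stats::plogis(model$platt_a * dv + model$platt_b)
}

#' Score every peptide x receptor pair
#'
#' Builds the outer-product features for all combinations of the supplied
#' peptides and full-length receptors, scores them with the model, and
#' flags pairs at or above `threshold` as predicted interactions. Scores
#' are invariant to input ordering.
#'
#' @param model A `cpi_model`.
#' @param peptides Named list of [peptidoform()] objects (or named
#'   character vector of sequences).
#' @param receptors Named list of [receptor_model()] objects; all must be
#'   full-length (use [filter_seven_tm()] first).
#' @param threshold Prediction threshold in \[0, 1\] (default 0.5).
#' @return A list with `scores` (data frame `peptide_id`, `receptor_id`,
#'   `score`) and `predicted` (the subset with `score >= threshold`).
#' @export
predict_pairs <- function(model, peptides, receptors, threshold = 0.5) {
  if (is.character(peptides)) {
    peptides <- lapply(peptides, peptidoform)
  }
  stopifnot(!is.null(names(peptides)), !is.null(names(receptors)))
  if (!all(vapply(receptors, is_full_length, logical(1)))) {
    stop("all receptors must be full-length (7 TM segments)")
  }
  pep_ids <- sort(names(peptides))
  rec_ids <- sort(names(receptors))
  pvecs <- lapply(peptides[pep_ids], peptide_descriptor)
  rvecs <- lapply(receptors[rec_ids], receptor_descriptor)
  rows <- expand.grid(receptor_id = rec_ids, peptide_id = pep_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  feats <- t(mapply(function(p, r) linearized_outer_product(pvecs[[p]], rvecs[[r]]),
                    rows$peptide_id, rows$receptor_id))
  scores <- data.frame(peptide_id = rows$peptide_id,
                       receptor_id = rows$receptor_id,
                       score = score_pairs(model, feats))
  list(scores = scores,
       predicted = scores[scores$score >= threshold, , drop = FALSE])
}

#' Choose representative peptide(s) for a family
#'
#' If all members are nested length-variants sharing a common C-terminus
#' (no structural variation), the longest peptide is selected. Otherwise
#' the family is split into at most two structure groups (average-linkage
#' clustering of pairwise edit distances) and each group contributes its
#' medoid (minimum summed edit distance; ties broken toward the longer,
#' then lexicographically smaller sequence).
#'
#' @param family Character vector of peptide sequences (or list of
#'   [peptidoform()]s), non-empty.
#' @param max_reps Maximum representatives (default 2).
#' @return Character vector of 1..`max_reps` representative sequences.
#' @export
choose_representative <- function(family, max_reps = 2L) {
  if (is.list(family)) family <- vapply(family, function(p) p$sequence, character(1))
  stopifnot(length(family) >= 1L)
  family <- unique(family)
  if (length(family) == 1L) return(family)
  nested <- all(vapply(family, function(s) {
    endsWith(family[which.max(nchar(family))], s)
  }, logical(1)))
  if (nested) {
    longest <- family[order(-nchar(family), family)][1]
    return(longest)
  }
  d <- utils::adist(family)
  dimnames(d) <- list(family, family)
  k <- min(max_reps, length(family))
  grp <- stats::cutree(stats::hclust(stats::as.dist(d), method = "average"), k = k)
  reps <- vapply(split(family, grp), function(members) {
    dd <- d[members, members, drop = FALSE]
    tot <- rowSums(dd)
    members[order(tot, -nchar(members), members)][1]
  }, character(1))
  unname(reps[order(names(reps))])
}

#' Top-scoring receptors per peptide
#'
#' Per-peptide ranking of receptors by score, truncated to `k`, without the
#' receptor-side injectivity of [assign_receptors()].
#'
#' @param scores Data frame with `peptide_id`, `receptor_id`, `score`.
#' @param k Receptors kept per peptide (default 5).
#' @return Data frame `peptide_id`, `receptor_id`, `score`, `rank`.
#' @export
top_receptors <- function(scores, k = 5L) {
  out <- do.call(rbind, lapply(split(scores, scores$peptide_id), function(df) {
    df <- df[order(-df$score, df$receptor_id), , drop = FALSE]
    df <- utils::head(df, k)
    df$rank <- seq_len(nrow(df))
    df
  }))
  rownames(out) <- NULL
  out
}

#' Assign receptors to peptides
#'
#' Each receptor is assigned to the peptide on which it attains its maximum
#' score (argmax over peptides; ties broken by peptide identifier order),
#' so a receptor belongs to at most one peptide. Per peptide, assigned
#' receptors are ranked by score and truncated to `max_per_peptide`.
#'
#' @param scores Data frame with `peptide_id`, `receptor_id`, `score`,
#'   complete over the grid under consideration.
#' @param max_per_peptide Keep at most this many receptors per peptide
#'   (default 5).
#' @return Data frame `peptide_id`, `receptor_id`, `score`, `rank`.
#' @export
assign_receptors <- function(scores, max_per_peptide = 5L) {
  stopifnot(all(c("peptide_id", "receptor_id", "score") %in% names(scores)))
  if (nrow(scores) == 0L) {
    return(data.frame(peptide_id = character(0), receptor_id = character(0),
                      score = numeric(0), rank = integer(0)))
  }
  # receptor -> argmax peptide
  ord <- order(scores$receptor_id, -scores$score, scores$peptide_id)
  s <- scores[ord, , drop = FALSE]
  best <- s[!duplicated(s$receptor_id), , drop = FALSE]
  # per peptide: rank descending and truncate
  out <- do.call(rbind, lapply(split(best, best$peptide_id), function(df) {
    df <- df[order(-df$score, df$receptor_id), , drop = FALSE]
    df <- utils::head(df, max_per_peptide)
    df$rank <- seq_len(nrow(df))
    df
  }))
  rownames(out) <- NULL
  out[order(out$peptide_id, out$rank), c("peptide_id", "receptor_id", "score", "rank")]
}
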