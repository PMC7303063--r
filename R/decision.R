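# The decision-complexity laboratory: visual tasks as classification over
# a perceptual encoding, under an explicit complexity budget.  Tasks are
# labeled generative specs; budgets cap the number of hyperplanes in the
# decision boundary, the number of feature dimensions, or the boundary
# curvature (kernel bandwidth floor).  Composing two tasks multiplies
# their class sets, which is why dual tasks are inherently more complex
# than their components.

#' Define a classification task
#'
#' @param classes named list of class samplers.  Each sampler is a
#'   `function(n)` returning an `n x d` numeric matrix of feature vectors
#'   (call it inside [with_seed()] or a seeded context for
#'   reproducibility).
#' @param priors class prior probabilities (default uniform); must sum
#'   to 1.
#' @param encoder name or description of the feature encoding (metadata).
#' @return object of class `task_spec`.
#' @export
task_spec <- function(classes, priors = NULL, encoder = "identity") {
  if (length(classes) < 1L || is.null(names(classes)) ||
      any(!nzchar(names(classes))))
    stop("`classes` must be a named list of samplers", call. = FALSE)
  if (!all(vapply(classes, is.function, TRUE)))
    stop("every class entry must be a sampler function(n)", call. = FALSE)
  if (is.null(priors)) priors <- rep(1 / length(classes), length(classes))
  if (length(priors) != length(classes) ||
      abs(sum(priors) - 1) > 1e-8 || any(priors < 0))
    stop("`priors` must be non-negative and sum to 1", call. = FALSE)
  structure(list(classes = classes, priors = priors, encoder = encoder),
            class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("<task_spec> %d classes (%s), encoder: %s\n",
              length(x$classes), paste(names(x$classes), collapse = ", "),
              x$encoder))
  invisible(x)
}

#' Gaussian toy task
#'
#' Convenience constructor: classes are spherical Gaussians at given means.
#' @param means list (or matrix rows) of class mean vectors.
#' @param sd common standard deviation.
#' @param names optional class names.
#' @return a [task_spec()].
#' @export
gaussian_task <- function(means, sd = 1, names = NULL) {
  if (is.matrix(means)) means <- split(means, row(means)[, 1])
  if (is.null(names)) names <- paste0("c", seq_along(means))
  cls <- stats::setNames(lapply(means, function(mu) {
    force(mu)
    function(n) {
      d <- length(mu)
      matrix(stats::rnorm(n * d, mean = rep(mu, each = n), sd = sd), n, d)
    }
  }), names)
  task_spec(cls, encoder = "identity")
}

#' Compose two tasks into a dual task
#'
#' The product task: one class per pair of component classes, features
#' concatenated.  Two 2-alternative tasks compose to a 4-alternative dual
#' task; class counts multiply.
#'
#' @param t1,t2 [task_spec()]s.
#' @return a [task_spec()] with `|C1| * |C2|` classes.
#' @export
compose_tasks <- function(t1, t2) {
  stopifnot(inherits(t1, "task_spec"), inherits(t2, "task_spec"))
  d1 <- ncol(t1$classes[[1]](1L)); d2 <- ncol(t2$classes[[1]](1L))
  if (is.null(d1) || is.null(d2))
    stop("component samplers must return matrices; encoders incompatible",
         call. = FALSE)
  classes <- list(); priors <- numeric(0)
  for (i in seq_along(t1$classes)) for (j in seq_along(t2$classes)) {
    f1 <- t1$classes[[i]]; f2 <- t2$classes[[j]]
    nm <- paste(names(t1$classes)[i], names(t2$classes)[j], sep = "x")
    classes[[nm]] <- local({
      a <- f1; b <- f2
      function(n) cbind(a(n), b(n))
    })
    priors <- c(priors, t1$priors[i] * t2$priors[j])
  }
  task_spec(classes, priors = priors,
            encoder = paste(t1$encoder, t2$encoder, sep = "+"))
}

#' Competing hypothesis count in multiple-object tracking
#'
#' Tracking `k` targets among `n` items means distinguishing the true
#' target set from every other k-subset: `choose(n, k) - 1` competing
#' hypotheses.  Tracking 4 of 9 items leaves 125 alternatives.
#'
#' @param n total items.
#' @param k tracked targets (0 <= k <= n).
#' @return integer count of competing hypotheses.
#' @export
mot_hypothesis_count <- function(n, k) {
  if (k > n || k < 0 || n < 0) stop("need 0 <= k <= n", call. = FALSE)
  as.integer(round(choose(n, k))) - 1L
}

#' Complexity budget for a classifier
#'
#' @param form `"hyperplanes"` (boundary built from at most `value` linear
#'   separators), `"dimensions"` (at most `value` feature dimensions used),
#'   or `"curvature"` (boundary curvature cap, realized as an RBF kernel
#'   bandwidth floor `1/value`).
#' @param value budget value (>= 1; `Inf` allowed for dimensions).
#' @return object of class `complexity_budget`.
#' @export
complexity_budget <- function(form = c("hyperplanes", "dimensions", "curvature"),
                              value) {
  form <- match.arg(form)
  if (!is.numeric(value) || length(value) != 1L || value < 1 && form != "curvature")
    stop("budget value must be >= 1", call. = FALSE)
  if (form == "curvature" && value <= 0)
    stop("curvature bound must be positive", call. = FALSE)
  structure(list(form = form, value = value), class = "complexity_budget")
}

# cells of a hyperplane arrangement: sign pattern -> integer key
cell_key <- function(X, W, b) {
  if (ncol(W) == 0L) return(rep(0, nrow(X)))
  Sg <- (X %*% W > matrix(b, nrow(X), length(b), byrow = TRUE)) + 0
  as.character(Sg %*% 2^(seq_len(ncol(W)) - 1))
}

fit_cells <- function(key, y) {
  tab <- tapply(y, key, function(v) names(which.max(table(v))))
  unlist(tab)
}

predict_cells <- function(key, cells, fallback) {
  out <- cells[key]
  out[is.na(out)] <- fallback
  unname(out)
}

# Greedy forward selection of k hyperplanes over a candidate pool (random
# directions, class-mean differences, coordinate axes; data-quantile
# thresholds), followed by coordinate-ascent refinement of each plane given
# the others.  A new plane is kept only when it improves training accuracy
# by a minimal margin — a complexity-control rule that also makes the
# fitted model nested in k (budget-(k-1) solutions are reused when no
# k-th plane earns its keep), so accuracy sweeps over k are monotone.
fit_hyperplanes <- function(X, y, k, n_candidates = 60, seed = 1,
                            min_gain = 0.002, refine_rounds = 2) {
  d <- ncol(X)
  fallback <- names(which.max(table(y)))
  cands <- with_seed(seed, {
    dirs <- matrix(stats::rnorm(n_candidates * d), n_candidates, d)
    mus <- do.call(rbind, lapply(split(as.data.frame(X), y), colMeans))
    if (nrow(mus) > 1) {
      pairs <- utils::combn(nrow(mus), 2)
      dirs <- rbind(dirs, mus[pairs[1, ], , drop = FALSE] -
                      mus[pairs[2, ], , drop = FALSE])
    }
    dirs <- rbind(dirs, diag(d))
    dirs / pmax(sqrt(rowSums(dirs^2)), 1e-12)
  })
  qs <- seq(0.1, 0.9, by = 0.1)
  projs <- X %*% t(cands)
  ths <- apply(projs, 2, stats::quantile, probs = qs, names = FALSE)
  yf <- as.integer(factor(y))
  ncls <- max(yf)
  n <- length(yf)
  # majority-vote training accuracy for an integer cell key
  acc_of_key <- function(key) {
    tab <- table(key, yf)
    sum(apply(tab, 1, max)) / n
  }
  # plane set kept as a bit matrix B (n x k) plus (ci, th) bookkeeping
  best_plane_given <- function(B, replace_at = NA) {
    fixed <- if (is.na(replace_at)) B else B[, -replace_at, drop = FALSE]
    base <- if (ncol(fixed)) as.vector(fixed %*% 2^(seq_len(ncol(fixed)) - 1)) else rep(0, n)
    mult <- 2^ncol(fixed)
    best <- list(acc = -1)
    for (ci in seq_len(nrow(cands))) {
      pj <- projs[, ci]
      for (th in ths[, ci]) {
        a <- acc_of_key(base + mult * (pj > th))
        if (a > best$acc) best <- list(acc = a, ci = ci, th = th)
      }
    }
    best
  }
  sel <- integer(0); thr <- numeric(0)
  B <- matrix(0, n, 0)
  acc <- max(tabulate(yf)) / n
  for (step in seq_len(k)) {
    cand <- best_plane_given(B)
    if (cand$acc < acc + min_gain) break
    sel <- c(sel, cand$ci); thr <- c(thr, cand$th)
    B <- cbind(B, (projs[, cand$ci] > cand$th) + 0)
    acc <- cand$acc
    if (ncol(B) > 1) {
      for (r in seq_len(refine_rounds)) {
        improved <- FALSE
        for (j in seq_len(ncol(B))) {
          cand <- best_plane_given(B, replace_at = j)
          if (cand$acc > acc + 1e-12) {
            sel <- c(sel[-j], cand$ci); thr <- c(thr[-j], cand$th)
            B <- cbind(B[, -j, drop = FALSE],
                       (projs[, cand$ci] > cand$th) + 0)
            acc <- cand$acc; improved <- TRUE
          }
        }
        if (!improved) break
      }
    }
  }
  W <- t(cands[sel, , drop = FALSE])
  key <- cell_key(X, W, thr)
  list(W = W, b = thr, cells = fit_cells(key, y), fallback = fallback,
       train_acc = acc)
}

#' Fit a complexity-budgeted classifier
#'
#' Draws seeded training and test samples from the task's class specs and
#' fits a classifier whose decision boundary respects the budget:
#' \describe{
#'   \item{hyperplanes}{a greedy arrangement of at most `k` linear
#'     separators; each cell of the arrangement takes its training-majority
#'     label.}
#'   \item{dimensions}{feature ranking by ANOVA F statistic, then linear
#'     discriminant analysis on the top `d` features (all features when
#'     `d = Inf`, the unrestricted case).}
#'   \item{curvature}{a support-vector machine with an RBF kernel whose
#'     bandwidth is floored at `1/value` — larger budgets allow curvier
#'     boundaries.}
#' }
#'
#' @param task a [task_spec()].
#' @param budget a [complexity_budget()].
#' @param n_train,n_test samples per draw (split across classes by prior).
#' @param seed RNG seed for sampling and fitting.
#' @return object of class `budgeted_classifier` with `model`, `budget`,
#'   `accuracy` (held-out), `accuracy_se` (binomial SE), `train_accuracy`.
#' @export
fit_budgeted_classifier <- function(task, budget, n_train = 400,
                                    n_test = 2000, seed = 1) {
  stopifnot(inherits(task, "task_spec"), inherits(budget, "complexity_budget"))
  draw <- function(n, seed_offset) with_seed(seed + seed_offset, {
    ns <- pmax(1L, round(n * task$priors))
    X <- do.call(rbind, lapply(seq_along(task$classes),
                               function(i) task$classes[[i]](ns[i])))
    list(X = X, y = factor(rep(names(task$classes), ns)))
  })
  tr <- draw(n_train, 0L); te <- draw(n_test, 1L)
  y <- as.character(tr$y)

  if (budget$form == "hyperplanes") {
    fit <- fit_hyperplanes(tr$X, y, k = budget$value, seed = seed + 2L)
    pred <- predict_cells(cell_key(te$X, fit$W, fit$b), fit$cells, fit$fallback)
    train_acc <- fit$train_acc
    model <- fit
  } else if (budget$form == "dimensions") {
    d_use <- min(budget$value, ncol(tr$X))
    Fstat <- vapply(seq_len(ncol(tr$X)), function(j)
      summary(stats::aov(tr$X[, j] ~ tr$y))[[1]]$`F value`[1], numeric(1))
    keep <- order(Fstat, decreasing = TRUE)[seq_len(d_use)]
    fit <- MASS::lda(tr$X[, keep, drop = FALSE], grouping = tr$y)
    pred <- as.character(stats::predict(fit, te$X[, keep, drop = FALSE])$class)
    train_acc <- mean(as.character(stats::predict(fit)$class) == y)
    model <- list(lda = fit, features = keep)
  } else {
    gam <- min(budget$value, 50)   # bandwidth floor 1/value
    fit <- e1071::svm(tr$X, tr$y, kernel = "radial", gamma = gam / 2,
                      cost = 10)
    pred <- as.character(stats::predict(fit, te$X))
    train_acc <- mean(as.character(stats::predict(fit, tr$X)) == y)
    model <- fit
  }
  acc <- mean(pred == as.character(te$y))
  structure(list(model = model, budget = budget, accuracy = acc,
                 accuracy_se = sqrt(acc * (1 - acc) / length(pred)),
                 train_accuracy = train_acc, n_test = length(pred)),
            class = "budgeted_classifier")
}

#' @export
print.budgeted_classifier <- function(x, ...) {
  cat(sprintf("<budgeted_classifier> %s budget %g: accuracy %.3f +/- %.3f\n",
              x$budget$form, x$budget$value, x$accuracy, x$accuracy_se))
  invisible(x)
}

#' Visual-working-memory confusability experiment
#'
#' Treats change detection as distinguishing the remembered array from all
#' arrays in which one item differs: for each set size, generates seeded
#' colored-square arrays and measures the encoder distance between each
#' array and a copy with one item recolored.  The summary is reported as
#' measured; whether one-item changes become relatively harder with set
#' size depends on the encoding.
#'
#' @param encoder `function(raster) -> numeric vector` mapping an
#'   H x W x 3 array to a fixed-length feature vector (see
#'   [stat_image_encoder()] and [pixel_encoder()]).
#' @param n_items_grid set sizes to test.
#' @param palette RGB palette matrix.
#' @param n_arrays seeded arrays per set size.
#' @param spec base [stimulus_spec()].
#' @param seed base seed.
#' @return data.frame: n_items, mean_change_distance, sd, n.
#' @export
vwm_experiment <- function(encoder, n_items_grid = c(2, 4, 8),
                           palette = default_palette(), n_arrays = 30,
                           spec = stimulus_spec("vwm_array", grid = c(3, 3)),
                           seed = 1) {
  d0 <- NULL
  rows <- lapply(n_items_grid, function(n) {
    ds <- vapply(seq_len(n_arrays), function(k) {
      sp <- spec; sp$seed <- seed + 1000 * n + k
      cp <- make_change_pair(sp, item = ((k - 1L) %% n) + 1L,
                             n_items = n, palette = palette)
      ea <- encoder(cp$a$raster); eb <- encoder(cp$b$raster)
      if (is.null(d0)) d0 <<- length(ea)
      if (length(ea) != d0 || length(eb) != d0)
        stop("encoder returned vectors of varying length", call. = FALSE)
      sqrt(sum((ea - eb)^2))
    }, numeric(1))
    data.frame(n_items = n, mean_change_distance = mean(ds),
               sd = stats::sd(ds), n = n_arrays)
  })
  do.call(rbind, rows)
}

#' Statistic-field image encoder
#'
#' Returns a closure mapping a raster (or [lum_img()]) to its flattened
#' summary-statistic field under a fixed geometry, for use in
#' [vwm_experiment()] and [scene_confusability()].
#'
#' @param ppd pixels per degree assumed for inputs.
#' @param fixation fixation (row, col) px, or NULL for image centre.
#' @param config [stat_config()].
#' @param g,d0 pooling parameters.
#' @return `function(raster) -> numeric vector`.
#' @export
stat_image_encoder <- function(ppd = 8, fixation = NULL,
                               config = stat_config(S = 3),
                               g = 0.5, d0 = 1.0) {
  scheme_cache <- new.env(parent = emptyenv())
  function(raster) {
    img <- if (inherits(raster, "lum_img")) raster
           else to_luminance(raster, ppd = ppd, fixation = fixation)
    key <- paste(dim(img$pixels), collapse = "x")
    sch <- scheme_cache[[key]]
    if (is.null(sch)) {
      sch <- build_pooling_scheme(img, g = g, d0 = d0)
      scheme_cache[[key]] <- sch
    }
    as_stat_numeric(compute_stat_field(img, sch, config))
  }
}

#' Raw pixel encoder
#' @param weights luminance conversion weights for color rasters.
#' @return `function(raster) -> numeric vector` (flattened luminance).
#' @export
pixel_encoder <- function(weights = c(0.2126, 0.7152, 0.0722)) {
  function(raster) {
    if (inherits(raster, "lum_img")) return(as.numeric(raster$pixels))
    if (length(dim(raster)) == 3L)
      as.numeric(weights[1] * raster[, , 1] + weights[2] * raster[, , 2] +
                   weights[3] * raster[, , 3])
    else as.numeric(raster)
  }
}

#' Scene confusability at a working-memory-derived precision
#'
#' Generalizes the change-detection precision to arbitrary stimuli: for a
#' set of seeded probe images, reports which other probes fall within
#' `threshold` of each probe in encoder space — the probe's confusable
#' set.  The threshold is typically the mean one-item-change distance from
#' [vwm_experiment()].
#'
#' @param encoder `function(raster) -> numeric vector`.
#' @param probes list of rasters (or [lum_img()]s).
#' @param threshold confusability distance threshold (> 0, or Inf).
#' @return list with `distance` (matrix), `confusable` (list of integer
#'   vectors, self included), `threshold`.
#' @export
scene_confusability <- function(encoder, probes, threshold) {
  if (length(probes) == 0L) stop("empty probe set", call. = FALSE)
  if (!is.numeric(threshold) || threshold < 0)
    stop("`threshold` must be non-negative", call. = FALSE)
  E <- do.call(rbind, lapply(probes, function(p) as.numeric(encoder(p))))
  D <- as.matrix(stats::dist(E))
  confusable <- lapply(seq_len(nrow(D)),
                       function(i) unname(which(D[i, ] <= threshold)))
  list(distance = D, confusable = confusable, threshold = threshold)
}
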