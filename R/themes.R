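# Theme stage: nonnegative matrix factorization of the topic-word
# matrix clusters topics into themes; Bayes' rule gives p(theme | word);
# per-message theme distributions, hard theme assignments, p(theme |
# disease) and disease-theme pointwise mutual information follow.

# Nonnegative double SVD initialization (positive/negative part split
# of each singular vector pair, larger side kept). Zeros are lifted to
# the matrix mean so multiplicative updates are not pinned at zero.
.nndsvd <- function(A, T) {
  s <- svd(A, nu = T, nv = T)
  W <- matrix(0, nrow(A), T)
  H <- matrix(0, T, ncol(A))
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  for (j in seq_len(T)[-1]) {
    u <- s$u[, j]; v <- s$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
    if (nup * nvp >= nun * nvn) {
      scale <- sqrt(s$d[j] * nup * nvp)
      if (nup > 0 && nvp > 0) {
        W[, j] <- scale * up / nup
        H[j, ] <- scale * vp / nvp
      }
    } else {
      scale <- sqrt(s$d[j] * nun * nvn)
      if (nun > 0 && nvn > 0) {
        W[, j] <- scale * un / nun
        H[j, ] <- scale * vn / nvn
      }
    }
  }
  lift <- mean(A)
  W[W <= 0] <- lift
  H[H <= 0] <- lift
  list(W = W, H = H)
}

# Lee-Seung multiplicative updates minimizing ||A - WH||_F.
.nmf_mu <- function(A, W, H, maxIter, tol) {
  eps <- .Machine$double.eps
  err <- numeric(maxIter + 1L)
  err[1] <- sqrt(sum((A - W %*% H)^2))
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    H <- H * (crossprod(W, A)) / (crossprod(W, W %*% H) + eps)
    W <- W * (A %*% t(H)) / (W %*% H %*% t(H) + eps)
    err[it + 1L] <- sqrt(sum((A - W %*% H)^2))
    if (abs(err[it] - err[it + 1L]) <= tol * max(err[1], eps)) break
  }
  list(W = W, H = H, err = err[seq_len(it + 1L)], converged = it < maxIter)
}

#' Cluster topics into themes by nonnegative matrix factorization
#'
#' Factorizes the topic-word matrix phi (K x V) as W H with W (K x T)
#' and H (T x V) nonnegative, minimizing Frobenius error by
#' multiplicative updates from a nonnegative-double-SVD initialization
#' (deterministic for a given model, so `seed` only matters for
#' downstream consumers that record it). Row-normalizing H gives
#' p(word | theme); the theme prior is proportional to the column mass
#' of W; Bayes' rule yields p(theme | word).
#'
#' @param model a fitted [TopicModel-class].
#' @param T number of themes (default 10), between 2 and K.
#' @param themeLabels optional character labels of length `T`; theme
#'   semantics are manual configuration, so defaults are "theme1"...
#' @param maxIter,tol multiplicative-update budget and relative
#'   convergence tolerance on the Frobenius error.
#' @param seed recorded seed (the factorization itself is
#'   deterministic).
#' @return a [ThemeModel-class].
#' @export
fitThemes <- function(model, T = 10L, themeLabels = NULL,
                      maxIter = 500L, tol = 1e-9, seed = 1L) {
  stopifnot(is(model, "TopicModel"))
  K <- nTopics(model)
  if (T > K) stop("number of themes T must not exceed K", call. = FALSE)
  if (T < 2L) stop("need at least 2 themes", call. = FALSE)
  phi <- topicWordDist(model)
  init <- .nndsvd(phi, T)
  fit <- .nmf_mu(phi, init$W, init$H, maxIter, tol)
  if (!fit$converged)
    warning("NMF did not converge within ", maxIter,
            " iterations; final Frobenius residual ",
            format(fit$err[length(fit$err)]))
  W <- fit$W; H <- fit$H
  colnames(H) <- colnames(phi)
  hs <- rowSums(H)
  degenerate <- hs <= 0
  hs[degenerate] <- 1
  pWordGivenTheme <- H / hs
  # an all-zero theme row (degenerate factorization) becomes uniform
  pWordGivenTheme[degenerate, ] <- 1 / ncol(H)
  themePrior <- colSums(W) / sum(W)
  pThemeGivenWord <- .posterior_given_word(pWordGivenTheme, themePrior)
  if (is.null(themeLabels)) themeLabels <- paste0("theme", seq_len(T))
  stopifnot(length(themeLabels) == T)
  colnames(W) <- themeLabels
  rownames(pWordGivenTheme) <- themeLabels
  colnames(pThemeGivenWord) <- themeLabels
  new("ThemeModel", W = W, H = H, pWordGivenTheme = pWordGivenTheme,
      pThemeGivenWord = pThemeGivenWord, themePrior = themePrior,
      themeNames = themeLabels, seed = as.integer(seed))
}

#' Per-message theme distributions and hard assignments
#'
#' p(theme | message) = sum_w p(w | message) p(theme | w), exactly as
#' for topic distributions. The hard assignment is the argmax theme,
#' ties broken toward the lowest theme index. Messages without
#' in-vocabulary tokens get `NA` loads and no assignment.
#'
#' @param corpus a [MessageCorpus-class].
#' @param themes a [ThemeModel-class].
#' @return list with `loads` (messages x T matrix, rownames = message
#'   ids) and `assigned` (named character vector of theme labels for
#'   defined messages).
#' @export
messageThemeLoads <- function(corpus, themes) {
  stopifnot(is(themes, "ThemeModel"))
  msgs <- messages(corpus)
  msgs <- msgs[!is.na(msgs$text), , drop = FALSE]
  loads <- .doc_loads(tokenizeText(msgs$text), themeGivenWord(themes))
  rownames(loads) <- msgs$message_id
  colnames(loads) <- themeNames(themes)
  defined <- rowSums(is.na(loads)) == 0
  assigned <- apply(loads[defined, , drop = FALSE], 1,
                    function(x) themeNames(themes)[which.max(x)])
  list(loads = loads, assigned = assigned)
}

#' Theme distribution per disease
#'
#' N(d, t) counts the disease-d messages hard-assigned to theme t;
#' p(t | d) = N(d, t) / N(d), reported as a percentage to two decimals
#' (half-up). Alternatively (`useHardAssignment = FALSE`) the expected
#' theme mass sum_m p(t | m) / N(d) is used instead of hard counts.
#'
#' @param assigned named character vector of hard assignments from
#'   [messageThemeLoads()] (or, when `useHardAssignment = FALSE`, the
#'   full `loads` matrix).
#' @param labels binary messages x diseases matrix.
#' @param themeLevels theme label universe (defaults to the labels seen).
#' @param useHardAssignment count argmax assignments (default) rather
#'   than summing probability mass.
#' @return data.frame `disease`, `theme`, `n`, `pThemeGivenDisease`,
#'   `pct`. Diseases with zero messages are omitted with a warning.
#' @export
themeGivenDisease <- function(assigned, labels, themeLevels = NULL,
                              useHardAssignment = TRUE) {
  if (useHardAssignment) {
    if (is.null(themeLevels)) themeLevels <- sort(unique(assigned))
    ids <- intersect(names(assigned), rownames(labels))
    rows <- list()
    for (d in colnames(labels)) {
      din <- ids[labels[ids, d] == 1]
      if (!length(din)) {
        warning("disease '", d, "' has no assigned messages; omitted")
        next
      }
      tab <- table(factor(assigned[din], levels = themeLevels))
      rows[[d]] <- data.frame(
        disease = d, theme = themeLevels, n = as.integer(tab),
        pThemeGivenDisease = as.numeric(tab) / length(din),
        pct = proportionPct(as.numeric(tab), length(din)),
        stringsAsFactors = FALSE)
    }
  } else {
    loads <- assigned
    if (is.null(themeLevels)) themeLevels <- colnames(loads)
    keep <- rowSums(is.na(loads)) == 0
    loads <- loads[keep, , drop = FALSE]
    ids <- intersect(rownames(loads), rownames(labels))
    rows <- list()
    for (d in colnames(labels)) {
      din <- ids[labels[ids, d] == 1]
      if (!length(din)) {
        warning("disease '", d, "' has no assigned messages; omitted")
        next
      }
      mass <- colSums(loads[din, , drop = FALSE])
      rows[[d]] <- data.frame(
        disease = d, theme = themeLevels, n = mass,
        pThemeGivenDisease = mass / length(din),
        pct = proportionPct(mass, length(din)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Disease-theme pointwise mutual information
#'
#' Over the universe of (disease, message) incidences with a theme
#' assignment: p(d) = N(d)/N, p(t) = N(., t)/N, p(d, t) = N(d, t)/N and
#' PMI(d, t) = log p(d, t) / (p(d) p(t)). PMI is 0 under independence
#' and positive when theme t is over-represented among disease-d
#' messages. Zero joint counts give `NA` (the -Inf case is not
#' reported numerically).
#'
#' @param stats data.frame from [themeGivenDisease()] (hard counts).
#' @param base logarithm base (default natural log).
#' @return `stats` with columns `pmi` appended.
#' @export
pmiDiseaseTheme <- function(stats, base = exp(1)) {
  N <- sum(stats$n)
  if (N <= 0) stop("no counts in theme statistics", call. = FALSE)
  nd <- tapply(stats$n, stats$disease, sum)
  nt <- tapply(stats$n, stats$theme, sum)
  pd <- nd[stats$disease] / N
  pt <- nt[stats$theme] / N
  pdt <- stats$n / N
  pmi <- log(pdt / (pd * pt), base = base)
  bad <- pd == 0 | pt == 0
  if (any(bad)) {
    warning("zero marginal for some disease or theme; PMI set to NA")
    pmi[bad] <- NA_real_
  }
  pmi[stats$n == 0] <- NA_real_
  stats$pmi <- as.numeric(pmi)
  stats
}
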