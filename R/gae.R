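# Graph auto-encoder enhancement of the cooperation network.
#
# A two-layer graph-convolutional encoder with ELU activation maps the node
# attribute matrix to latent representations Z; an inner-product decoder
# reconstructs the adjacency. Training minimizes
#   L_total = L_rec + lambda1 * L_fc + lambda2 * L_mp
# where L_rec is an MSE reconstruction loss (with per-epoch negative
# sampling), L_fc ties the Gaussian interaction profile (GIP) kernel
# similarity of Z to that of the disease-association profiles, and L_mp is a
# supervised-contrastive "difference prompt" pulling together features that
# share a differential-expression pseudo-label. Gradients are analytic
# (verified against finite differences in the test suite) and optimized with
# Adam.

#' Symmetrically normalized adjacency with self-loops
#'
#' Returns `D^(-1/2) (A + I) D^(-1/2)` where `D` is the degree matrix of
#' `A + I`. Self-loops guarantee positive degrees, so the result is always
#' defined.
#'
#' @param A symmetric binary adjacency matrix with zero diagonal.
#' @return symmetric real matrix of the same dimension.
#' @export
normalized_adjacency <- function(A) {
  A <- as.matrix(A)
  At <- A + diag(nrow(A))
  d <- rowSums(At)
  s <- 1 / sqrt(d)
  At * outer(s, s)
}

#' @keywords internal
elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)

#' @keywords internal
elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))

#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize encoder and discriminator weights
#'
#' Seeded scaled-uniform (fan-based, Glorot-style) initialization drawn from
#' the ambient RNG; callers seed it.
#'
#' @param in_dim attribute width (p + n).
#' @param hidden_dims the two encoder widths.
#' @param discr_dim discriminator output width.
#' @return list with matrices `W0`, `W1`, `DL`.
#' @export
gae_init_params <- function(in_dim, hidden_dims, discr_dim) {
  glorot <- function(fin, fout) {
    lim <- sqrt(6 / (fin + fout))
    matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
  }
  list(W0 = glorot(in_dim, hidden_dims[1]),
       W1 = glorot(hidden_dims[1], hidden_dims[2]),
       DL = glorot(hidden_dims[2], discr_dim))
}

#' Encode node attributes into latent representations
#'
#' `Z = A_hat %*% ELU(A_hat %*% X %*% W0) %*% W1` with ELU alpha = 1.
#'
#' @param A_hat normalized adjacency from [normalized_adjacency()].
#' @param X node attribute matrix (m x (p + n)).
#' @param params parameter list from [gae_init_params()].
#' @return m x h2 latent matrix, rows aligned with the node order.
#' @export
gae_encode <- function(A_hat, X, params) {
  if (ncol(A_hat) != nrow(X) || ncol(X) != nrow(params$W0) ||
      ncol(params$W0) != nrow(params$W1))
    stop("dimension mismatch in encoder inputs", call. = FALSE)
  A_hat %*% elu(A_hat %*% X %*% params$W0) %*% params$W1
}

#' Inner-product decoder
#'
#' `A_rec = sigmoid(Z %*% t(Z))`; symmetric with entries in (0, 1).
#'
#' @param Z latent matrix.
#' @return m x m reconstruction probability matrix.
#' @export
gae_decode <- function(Z) sigmoid(Z %*% t(Z))

#' Sample the reconstruction entry set for one epoch
#'
#' All positive (edge) pairs plus `ratio` times as many non-edge pairs drawn
#' uniformly without replacement from the ambient RNG; pairs are upper
#' triangular (each undirected pair once). Returns `NULL` (full-matrix mode,
#' with a message) when the graph has no edges.
#'
#' @keywords internal
sample_rec_entries <- function(A, ratio = 1.0) {
  ut <- which(upper.tri(A))
  pos <- ut[A[ut] > 0]
  if (length(pos) == 0L) {
    message("graph has no edges; reconstruction loss uses the full matrix")
    return(NULL)
  }
  neg <- ut[A[ut] == 0]
  take <- min(length(neg), round(ratio * length(pos)))
  sel <- c(pos, if (take > 0) sample(neg, take) else integer(0))
  arrayInd(sel, dim(A))
}

#' Mean-squared reconstruction error
#'
#' Over the full matrix (`entries = NULL`) or over a sampled entry set of
#' (row, col) index pairs, each counted once.
#'
#' @param A_co binary adjacency.
#' @param A_rec decoder output of the same shape.
#' @param entries optional 2-column index matrix from the negative sampler.
#' @return nonnegative scalar.
#' @export
reconstruction_loss <- function(A_co, A_rec, entries = NULL) {
  stopifnot(all(dim(A_co) == dim(A_rec)))
  if (is.null(entries)) return(mean((A_co - A_rec)^2))
  mean((A_co[entries] - A_rec[entries])^2)
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' `S_ij = exp(-r * ||v_i - v_j||^2)` with bandwidth
#' `r = r' / mean_k(||v_k||^2)` and `r' = 1` by default. Applied both to
#' disease-association profiles and to latent representations, each with its
#' own bandwidth.
#'
#' @param vectors numeric matrix, one profile per row.
#' @param bandwidth_scale the scale r'.
#' @return symmetric similarity matrix with unit diagonal, entries in (0, 1].
#' @export
gip_similarity <- function(vectors, bandwidth_scale = 1) {
  v <- as.matrix(vectors)
  sq <- rowSums(v^2)
  mu <- mean(sq)
  if (mu == 0)
    stop("all profiles are zero; GIP bandwidth undefined", call. = FALSE)
  r <- bandwidth_scale / mu
  d2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(v), 0)
  exp(-r * d2)
}

#' Functional-consistency loss
#'
#' Squared Frobenius norm of the difference between the knowledge-side and
#' representation-side GIP similarity matrices.
#'
#' @param GS,GSp similarity matrices of identical shape.
#' @return nonnegative scalar.
#' @export
functional_consistency_loss <- function(GS, GSp) {
  if (!all(dim(GS) == dim(GSp)))
    stop("similarity matrices must have the same shape", call. = FALSE)
  sum((GS - GSp)^2)
}

#' Assign differential-expression pseudo-labels
#'
#' Per-feature two-sided t-test on the raw expression values; p < 0.05 maps
#' to `"y0"` (differential), otherwise `"y1"`. Degenerate features (zero
#' variance in both groups with equal means) get `"y1"` with a message.
#'
#' @param data an [expression_dataset()].
#' @param variant `"welch"` or `"student"`.
#' @return named character vector over features with values `"y0"`/`"y1"`.
#' @export
assign_pseudo_labels <- function(data, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  p <- vapply(seq_len(n_features(data)), function(i) {
    suppressMessages(
      edge_significance(data$values[, i], data$labels, variant = variant))
  }, numeric(1))
  stats::setNames(ifelse(p < 0.05, "y0", "y1"), colnames(data$values))
}

#' Supervised-contrastive difference-prompt loss
#'
#' Discriminator outputs `u_i = normalize(D_L' z_i)` (normalization optional)
#' enter a temperature-scaled contrastive loss: each feature is pulled toward
#' features sharing its pseudo-label and pushed from the rest. Features whose
#' pseudo-label class is a singleton contribute no term (reported with a
#' message). Log-sum-exp stabilized.
#'
#' @param Z latent matrix (m x h2), m >= 2.
#' @param labels pseudo-label vector of length m.
#' @param DL discriminator weight matrix (h2 x h_d).
#' @param tau temperature (> 0).
#' @param normalize L2-normalize discriminator outputs first.
#' @return nonnegative scalar.
#' @export
difference_prompt_loss <- function(Z, labels, DL, tau = 0.1, normalize = TRUE) {
  m <- nrow(Z)
  if (m < 2L) stop("contrastive loss needs at least 2 nodes", call. = FALSE)
  U <- Z %*% DL
  if (normalize) {
    nrm <- pmax(sqrt(rowSums(U^2)), 1e-12)
    U <- U / nrm
  }
  logits <- tcrossprod(U) / tau
  diag(logits) <- -Inf
  same <- outer(labels, labels, "==")
  diag(same) <- FALSE
  nb <- rowSums(same)
  active <- nb >= 1L
  if (any(!active))
    message(sum(!active), " node(s) with a singleton pseudo-label class ",
            "skipped in the contrastive loss")
  if (!any(active)) return(0)
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  logp <- logits - lse            # log softmax over a != i
  diag(logp) <- 0                 # excluded; avoids -Inf * 0
  -sum((rowSums(logp * same) / pmax(nb, 1))[active])
}

#' Combine the loss components
#'
#' `L_total = L_rec + lambda1 * L_fc + lambda2 * L_mp`; terms switched off by
#' the ablation flags contribute zero.
#'
#' @param components numeric vector or list `(l_rec, l_fc, l_mp)`.
#' @param lambda1,lambda2 nonnegative weights.
#' @param use_knowledge,use_difference_prompt ablation flags.
#' @return nonnegative scalar.
#' @export
total_loss <- function(components, lambda1, lambda2,
                       use_knowledge = TRUE, use_difference_prompt = TRUE) {
  if (lambda1 < 0 || lambda2 < 0)
    stop("loss weights must be nonnegative", call. = FALSE)
  components <- as.numeric(unlist(components))
  l_rec <- components[1]
  l_fc <- if (use_knowledge) components[2] else 0
  l_mp <- if (use_difference_prompt) components[3] else 0
  l_rec + lambda1 * l_fc + lambda2 * l_mp
}

# Loss + analytic gradients of L_total wrt (W0, W1, DL).
# `entries` selects the reconstruction entry set (NULL = full matrix);
# `GS` is NULL under use_knowledge = FALSE, `plabels` NULL under
# use_difference_prompt = FALSE.
#' @keywords internal
gae_loss_grad <- function(params, A_hat, X, A_co, entries, GS, plabels,
                          config) {
  m <- nrow(A_co)
  AX <- A_hat %*% X
  H0 <- AX %*% params$W0
  H1 <- elu(H0)
  AH1 <- A_hat %*% H1
  Z <- AH1 %*% params$W1

  GZ <- matrix(0, nrow(Z), ncol(Z))

  ## reconstruction term
  S <- tcrossprod(Z)
  P <- sigmoid(S)
  if (is.null(entries)) {
    l_rec <- mean((A_co - P)^2)
    M <- (-2 / (m * m)) * (A_co - P) * P * (1 - P)
    GZ <- GZ + (M + t(M)) %*% Z
  } else {
    err <- A_co[entries] - P[entries]
    l_rec <- mean(err^2)
    M <- matrix(0, m, m)
    M[entries] <- (-2 / nrow(entries)) * err * P[entries] * (1 - P[entries])
    GZ <- GZ + (M + t(M)) %*% Z
  }

  ## functional-consistency term
  l_fc <- 0
  if (!is.null(GS) && config$lambda1 > 0) {
    sq <- rowSums(Z^2)
    mu <- mean(sq)
    if (mu == 0)
      stop("latent representations collapsed to zero; GIP undefined",
           call. = FALSE)
    r <- 1 / mu
    D2 <- pmax(outer(sq, sq, "+") - 2 * S, 0)
    GSp <- exp(-r * D2)
    Delta <- GS - GSp
    l_fc <- sum(Delta^2)
    G <- -2 * Delta                 # dL/dGSp
    Pmat <- G * (-r * GSp)          # dL/dD2 (symmetric)
    GZ_fc <- 4 * (rowSums(Pmat) * Z - Pmat %*% Z)
    c_r <- sum(G * (-D2 * GSp))     # dL/dr
    GZ_fc <- GZ_fc + c_r * (-1 / mu^2) * (2 / m) * Z
    GZ <- GZ + config$lambda1 * GZ_fc
  } else if (!is.null(GS)) {
    GSp <- gip_similarity(Z)
    l_fc <- sum((GS - GSp)^2)
  }

  ## difference-prompt term
  l_mp <- 0
  G_DL <- matrix(0, nrow(params$DL), ncol(params$DL))
  if (!is.null(plabels)) {
    tau <- config$tau
    V <- Z %*% params$DL
    if (config$normalize_discriminator) {
      nrm <- pmax(sqrt(rowSums(V^2)), 1e-12)
      U <- V / nrm
    } else {
      U <- V
    }
    logits <- tcrossprod(U) / tau
    diag(logits) <- -Inf
    same <- outer(plabels, plabels, "==")
    diag(same) <- FALSE
    nb <- rowSums(same)
    active <- nb >= 1L
    if (any(active)) {
      mx <- apply(logits, 1, max)
      lse <- mx + log(rowSums(exp(logits - mx)))
      logp <- logits - lse
      Pr <- exp(logp)
      diag(Pr) <- 0
      diag(logp) <- 0             # excluded; avoids -Inf * 0
      l_mp <- -sum((rowSums(logp * same) / pmax(nb, 1))[active])
      Q <- (Pr - same / pmax(nb, 1)) / tau
      Q[!active, ] <- 0
      GU <- (Q + t(Q)) %*% U
      if (config$normalize_discriminator) {
        dotg <- rowSums(GU * U)
        GV <- (GU - dotg * U) / nrm
      } else {
        GV <- GU
      }
      G_DL <- crossprod(Z, GV)
      GZ <- GZ + config$lambda2 * (GV %*% t(params$DL))
    }
  }

  ## backprop through the encoder
  G_W1 <- crossprod(AH1, GZ)
  G_H1 <- A_hat %*% GZ %*% t(params$W1)
  G_H0 <- G_H1 * elu_grad(H0)
  G_W0 <- crossprod(AX, G_H0)

  l_total <- l_rec + config$lambda1 * l_fc + config$lambda2 * l_mp
  list(l_rec = l_rec, l_fc = l_fc, l_mp = l_mp, l_total = l_total,
       Z = Z,
       grads = list(W0 = G_W0, W1 = G_W1, DL = config$lambda2 * G_DL))
}

#' Train the graph auto-encoder on a cooperation network
#'
#' Initializes weights with a seeded fan-scaled uniform scheme, then runs
#' `config$epochs` Adam steps on the total loss. All stochastic steps
#' (initialization, per-epoch negative sampling) draw from one generator
#' seeded from `config$seed`, so identical seed + config reproduce the run
#' bit for bit.
#'
#' @param net a [build_cooperation_network()] result.
#' @param knowledge a [knowledge_table()] aligned (or alignable) to the
#'   network nodes; ignored under `use_knowledge = FALSE`.
#' @param data the training [expression_dataset()] (for pseudo-labels).
#' @param config a [run_config()].
#' @return list with `params`, `Z` (final latent matrix, rows named by
#'   node), and `trace` (per-epoch data.frame of `l_rec`, `l_fc`, `l_mp`,
#'   `l_total`).
#' @export
train_gae <- function(net, knowledge, data, config = run_config()) {
  A_co <- net$graph$weights
  # z-score attribute columns across nodes: keeps initial latent dot
  # products out of the decoder's saturated range regardless of the
  # expression scale the user supplies
  X <- standardize_columns(net$attributes)$x
  ids <- net$graph$node_ids
  A_hat <- normalized_adjacency(A_co)

  GS <- NULL
  if (config$use_knowledge) {
    kn <- align_knowledge(knowledge, ids)
    GS <- gip_similarity(kn$assoc)
  }
  plabels <- NULL
  if (config$use_difference_prompt)
    plabels <- unname(assign_pseudo_labels(data, config$t_test_variant)[ids])

  with_seed(derive_seed(config$seed, 101L), {
    params <- gae_init_params(ncol(X), config$hidden_dims, config$discr_dim)
    opt <- adam_state(params)
    n_ep <- config$epochs
    trace <- data.frame(epoch = integer(0), l_rec = numeric(0),
                        l_fc = numeric(0), l_mp = numeric(0),
                        l_total = numeric(0))
    if (n_ep > 0) {
      trace <- data.frame(epoch = seq_len(n_ep), l_rec = NA_real_,
                          l_fc = NA_real_, l_mp = NA_real_,
                          l_total = NA_real_)
      for (ep in seq_len(n_ep)) {
        entries <- if (config$use_neg_sampling) {
          suppressMessages(sample_rec_entries(A_co, config$neg_sample_ratio))
        } else NULL
        res <- gae_loss_grad(params, A_hat, X, A_co, entries, GS, plabels,
                             config)
        if (!is.finite(res$l_total))
          stop("non-finite loss at epoch ", ep, call. = FALSE)
        upd <- adam_step(opt, params, res$grads, config$learning_rate)
        params <- upd$params
        opt <- upd$state
        trace[ep, ] <- list(ep, res$l_rec, res$l_fc, res$l_mp, res$l_total)
      }
    }
    Z <- gae_encode(A_hat, X, params)
    rownames(Z) <- ids
    list(params = params, Z = Z, trace = trace,
         seed = derive_seed(config$seed, 101L))
  })
}

#' @keywords internal
adam_state <- function(params) {
  list(t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

#' @keywords internal
adam_step <- function(state, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Derive the enhanced interaction network from latent representations
#'
#' Candidate weight `w_ij = sigmoid(z_i . z_j)`; an edge is kept iff
#' `w_ij >= theta` (the decoder's natural decision boundary at the default
#' 0.5). When `candidates` is supplied, only its edges are eligible: the
#' enhanced network then denoises the cooperation network by dropping edges
#' whose reconstruction probability falls below `theta` and reweighting the
#' rest, rather than proposing new pairs. All nodes are retained, so
#' isolates are allowed.
#'
#' @param Z latent matrix.
#' @param node_ids node identifiers (default: rownames of `Z`).
#' @param theta edge-keeping threshold in (0, 1).
#' @param candidates optional [weighted_graph()] (typically the binary
#'   cooperation network) whose edge set limits the candidate pairs.
#' @return a [weighted_graph()] with edge weights in (0, 1).
#' @export
build_enhanced_network <- function(Z, node_ids = rownames(Z), theta = 0.5,
                                   candidates = NULL) {
  W <- sigmoid(tcrossprod(as.matrix(Z)))
  W[W < theta] <- 0
  diag(W) <- 0
  if (!is.null(candidates)) {
    stopifnot(inherits(candidates, "weighted_graph"))
    W <- W * (candidates$weights[node_ids, node_ids] > 0)
  }
  weighted_graph(W, node_ids)
}
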