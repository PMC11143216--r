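# Internal likelihood engine.
#
# Every quantity the package computes from the generative model goes through
# this file: complete-data log-joints, closed-form marginal log-joints under
# arbitrary missingness, predictive outcome probabilities, and analytic
# gradients for training. The model is linear-Gaussian in (A_miss, f) with a
# logistic outcome head, so for any missingness pattern:
#
#   * missing binary covariates are enumerated (outermost, <= 2^k terms),
#   * missing continuous covariates and a missing image are integrated
#     analytically inside each term,
#   * the leftover logistic-Gaussian integral for the outcome factor is
#     approximated by the scaled-probit rule
#       E[sigma(eta)] ~ sigma(m / sqrt(1 + (pi/8) s^2)),
#     with (m, s^2) the posterior moments of the linear argument eta.
#
# Rows are grouped by missingness pattern; within a (group x enumeration
# term) all covariance-type quantities are shared and the row-specific work
# is plain matrix algebra, which keeps full-cohort evaluation and gradient
# accumulation fast in R.

PROBIT_SCALE <- pi / 8

# Convert a cohort tibble into the internal batch representation.
as_batch <- function(data, schema, d_f, d_J) {
  check_cohort(data, schema)
  n <- nrow(data)
  A <- as.matrix(data[, schema$names, drop = FALSE])
  storage.mode(A) <- "double"

  jn <- j_names(data)
  if (length(jn) > d_J) {
    abort(paste0("cohort has ", length(jn), " J_ columns but model expects ", d_J))
  }
  J <- matrix(NA_real_, n, d_J)
  if (length(jn)) J[, seq_along(jn)] <- as.matrix(data[, jn, drop = FALSE])

  fn <- f_names(data)
  FM <- NULL
  img <- rep(FALSE, n)
  if (length(fn)) {
    if (length(fn) != d_f) {
      abort(paste0("cohort has ", length(fn), " f_ columns but model expects ", d_f))
    }
    FM <- as.matrix(data[, paste0("f_", seq_len(d_f)), drop = FALSE])
    cc <- rowSums(is.na(FM))
    if (any(cc > 0 & cc < d_f)) {
      abort("image features must be fully present or fully missing per row")
    }
    img <- cc == 0
  }
  y <- if ("y" %in% names(data)) as.numeric(data$y) else rep(NA_real_, n)

  amask <- !is.na(A)
  jmask <- !is.na(J)
  key <- paste(
    apply(amask, 1, paste, collapse = ""),
    if (d_J > 0) apply(jmask, 1, paste, collapse = "") else rep("", n),
    as.integer(img),
    sep = "|"
  )
  list(
    A = A, J = J, FM = FM, img = img, y = y, n = n,
    amask = amask, jmask = jmask, key = key, schema = schema
  )
}

chol_spd <- function(M) {
  out <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(out)) {
    inform("adding 1e-9 jitter to a non-PD covariance factorization")
    out <- chol(M + diag(1e-9, nrow(M)))
  }
  out
}

new_grad <- function(d_A, d_f, d_J) {
  list(
    beta = matrix(0, d_A, d_f), phi = matrix(0, d_f, d_J),
    alpha_I = numeric(d_f), alpha_A = numeric(d_A),
    b_Y = 0, D = 0, E = 0
  )
}

# Core evaluator. mode = "joint" needs y and returns per-row marginal
# log-joints log p(observed, Y); mode = "predict" returns p(Y = 1 | observed).
# rw: per-row weights applied to the gradient accumulation (e.g. 1/n).
tavr_engine <- function(batch, params, prior, mode = c("joint", "predict"),
                        use_aux = TRUE, want_grad = FALSE, rw = NULL) {
  mode <- match.arg(mode)
  d_A <- params$d_A
  d_f <- params$d_f
  d_J <- params$d_J
  beta <- params$beta
  phi <- params$phi
  aI <- params$alpha_I
  aA <- params$alpha_A
  bY <- params$b_Y
  D <- exp(2 * params$log_sigma_I)
  E <- exp(2 * params$log_sigma_J)
  sch <- batch$schema
  cont <- schema_cont(sch)
  n <- batch$n
  if (is.null(rw)) rw <- rep(1, n)

  if (mode == "joint" && anyNA(batch$y)) {
    abort("outcome y is missing for some rows; use predictive_outcome for prediction")
  }

  out_ll <- numeric(n)
  out_pred <- numeric(n)
  grad <- if (want_grad) new_grad(d_A, d_f, d_J) else NULL
  grad_F <- if (want_grad && !is.null(batch$FM)) matrix(0, n, d_f) else NULL

  jmask_eff <- batch$jmask
  if (!use_aux) jmask_eff[] <- FALSE

  groups <- split(seq_len(n), if (use_aux) batch$key else
    paste(apply(batch$amask, 1, paste, collapse = ""), as.integer(batch$img)))

  for (idx in groups) {
    r1 <- idx[1]
    amiss <- which(!batch$amask[r1, ])
    S <- intersect(amiss, cont)
    Bm <- setdiff(amiss, S)
    Jobs <- which(jmask_eff[r1, ])
    img <- batch$img[r1]
    obsA <- setdiff(seq_len(d_A), amiss)
    ng <- length(idx)

    if (length(Bm) > 20) {
      abort(paste0(
        "refusing to enumerate ", length(Bm),
        " missing binary covariates (> 20); reduce the pattern"
      ))
    }

    # shared covariance-type quantities -------------------------------
    mS <- prior$mean[S]
    Vs <- prior$var[S]
    R <- beta[S, , drop = FALSE]
    VR <- Vs * R # V %*% R
    Sig <- diag(D, d_f) + crossprod(R, VR)
    gam <- aA[S] - as.numeric(R %*% aI)
    vg <- Vs * gam

    y <- batch$y[idx]
    Arows <- batch$A[idx, , drop = FALSE]
    w_rw <- rw[idx]

    # observed-dims prior term (combo-independent, rows)
    lpA <- numeric(ng)
    for (k in obsA) {
      if (sch$kinds[k] == "continuous") {
        lpA <- lpA + dnorm(Arows[, k], prior$mean[k], sqrt(prior$var[k]), log = TRUE)
      } else {
        rk <- prior$rate[k]
        lpA <- lpA + Arows[, k] * log(rk) + (1 - Arows[, k]) * log(1 - rk)
      }
    }

    # enumeration of missing binary covariates
    nb <- 2^length(Bm)
    cb <- if (length(Bm)) {
      as.matrix(expand.grid(rep(list(c(0, 1)), length(Bm))))
    } else {
      matrix(0, 1, 0)
    }
    logw <- if (length(Bm)) {
      rk <- prior$rate[Bm]
      as.numeric(cb %*% log(rk) + (1 - cb) %*% log(1 - rk))
    } else {
      0
    }

    if (img) {
      # ---- image present: f observed ------------------------------
      FMr <- batch$FM[idx, , drop = FALSE]
      ch <- chol_spd(Sig)
      P <- chol2inv(ch)
      logdetSig <- 2 * sum(log(diag(ch)))
      V_post <- if (length(S)) diag(Vs, length(S)) - VR %*% P %*% t(VR) else
        matrix(0, 0, 0)
      q_v <- if (length(S)) as.numeric(P %*% crossprod(R, vg)) else numeric(d_f)
      Vpg <- if (length(S)) as.numeric(V_post %*% gam) else numeric(0)
      s2 <- max(0, sum(gam * Vpg))
      r_sc <- 1 / sqrt(1 + PROBIT_SCALE * s2)
      w_A <- aA - as.numeric(beta %*% aI)

      # measurement factor: depends on f only, combo-independent
      q <- length(Jobs)
      if (q) {
        res <- batch$J[idx, Jobs, drop = FALSE] - FMr %*% phi[, Jobs, drop = FALSE]
        l_J <- -0.5 * rowSums(res^2) / E - 0.5 * q * log(2 * pi * E)
      } else {
        l_J <- numeric(ng)
      }

      LWmat <- matrix(0, ng, nb) # f-density + enumeration weight per combo
      Zmat <- matrix(0, ng, nb) # probit argument per combo
      st <- vector("list", nb) # per-combo state for the gradient pass
      for (b in seq_len(nb)) {
        Abar <- Arows
        if (length(S)) Abar[, S] <- rep(mS, each = ng)
        if (length(Bm)) Abar[, Bm] <- rep(cb[b, ], each = ng)
        A_o <- Abar
        if (length(S)) A_o[, S] <- 0
        T_ <- Abar %*% beta
        Delta <- FMr - T_
        U <- Delta %*% P
        l_f <- -0.5 * rowSums(Delta * U) - 0.5 * logdetSig - 0.5 * d_f * log(2 * pi)
        M_post <- if (length(S)) {
          sweep(U %*% t(VR), 2, mS, "+")
        } else {
          matrix(0, ng, 0)
        }
        c0 <- as.numeric(A_o %*% w_A) + bY
        m_eta <- c0 + as.numeric(FMr %*% aI) +
          if (length(S)) as.numeric(M_post %*% gam) else 0
        z <- m_eta * r_sc
        LWmat[, b] <- l_f + logw[b]
        Zmat[, b] <- z
        if (want_grad) {
          st[[b]] <- list(
            Abar = Abar, A_o = A_o, U = U, M_post = M_post, m_eta = m_eta
          )
        }
      }
      if (mode == "joint") {
        Lmat <- LWmat + batch_y_term(Zmat, y)
        lse <- apply(Lmat, 1, max)
        ll_noJ <- lse + log(rowSums(exp(Lmat - lse)))
        out_ll[idx] <- ll_noJ + l_J + lpA
      } else {
        # combo weights from the f-density only (J and prior cancel)
        wmax <- apply(LWmat, 1, max)
        Wn <- exp(LWmat - wmax)
        Wn <- Wn / rowSums(Wn)
        out_pred[idx] <- rowSums(Wn * plogis(Zmat))
      }
      if (want_grad) {
        Pw <- exp(Lmat - ll_noJ) # posterior combo weights per row
        if (q) {
          grad$phi[, Jobs] <- grad$phi[, Jobs] +
            crossprod(FMr, w_rw * res) / E
          grad$E <- grad$E +
            sum(w_rw * (-0.5 * q / E + 0.5 * rowSums(res^2) / E^2))
        }
        gF_acc <- if (!is.null(grad_F)) {
          (if (q) w_rw * (res %*% t(phi[, Jobs, drop = FALSE])) / E else
            matrix(0, ng, d_f))
        } else {
          NULL
        }
        for (b in seq_len(nb)) {
          sb <- st[[b]]
          w <- w_rw * Pw[, b]
          p <- plogis(Zmat[, b])
          gmr <- (y - p) * r_sc
          gsr <- (y - p) * sb$m_eta * (-PROBIT_SCALE / 2) * r_sc^3
          gm <- w * gmr
          gs <- w * gsr
          sw <- sum(w)
          sgs <- sum(gs)
          U <- sb$U
          # f-density
          grad$beta <- grad$beta + crossprod(sb$Abar, w * U)
          Gw <- crossprod(U, w * U) - sw * P
          if (length(S)) {
            grad$beta[S, ] <- grad$beta[S, ] + VR %*% Gw
          }
          grad$D <- grad$D + 0.5 * (sum(w * rowSums(U * U)) - sw * sum(diag(P)))
          # outcome factor
          su1 <- as.numeric(crossprod(U, gm))
          sgm_Ao <- as.numeric(crossprod(sb$A_o, gm))
          sgm_Abar <- as.numeric(crossprod(sb$Abar, gm))
          sgm_F <- as.numeric(crossprod(FMr, gm))
          grad$b_Y <- grad$b_Y + sum(gm)
          grad$alpha_A <- grad$alpha_A + sgm_Ao
          grad$alpha_I <- grad$alpha_I + sgm_F - as.numeric(crossprod(beta, sgm_Ao))
          grad$beta <- grad$beta - outer(sgm_Ao, aI)
          if (length(S)) {
            gambar <- as.numeric(crossprod(sb$M_post, gm)) + 2 * sgs * Vpg
            grad$alpha_A[S] <- grad$alpha_A[S] + gambar
            grad$alpha_I <- grad$alpha_I - as.numeric(crossprod(R, gambar))
            grad$beta <- grad$beta - outer(sgm_Abar, q_v)
            gR <- -outer(gambar, aI) +
              outer(vg, su1) - outer(as.numeric(VR %*% su1), q_v) -
              outer(as.numeric(VR %*% q_v), su1) +
              sgs * (-2 * outer(vg, q_v) + 2 * outer(as.numeric(VR %*% q_v), q_v))
            grad$beta[S, ] <- grad$beta[S, ] + gR
            grad$D <- grad$D - sum(q_v * su1) + sgs * sum(q_v^2)
          }
          if (!is.null(gF_acc)) {
            gF_acc <- gF_acc - (w * U) + outer(gm, aI + q_v)
          }
        }
        if (!is.null(grad_F)) grad_F[idx, ] <- gF_acc
      }
    } else {
      # ---- image missing: f latent --------------------------------
      q <- length(Jobs)
      Phi <- phi[, Jobs, drop = FALSE]
      c_all <- as.numeric(crossprod(R, vg) + Sig %*% aI)
      VarEta <- sum(gam * vg) + 2 * sum(vg * (R %*% aI)) +
        as.numeric(crossprod(aI, Sig %*% aI))
      if (q) {
        Sx <- crossprod(Phi, Sig %*% Phi) + diag(E, q)
        chx <- chol_spd(Sx)
        Qx <- chol2inv(chx)
        logdetSx <- 2 * sum(log(diag(chx)))
        kap <- as.numeric(crossprod(Phi, c_all))
        rho <- as.numeric(Qx %*% kap)
        s2 <- max(0, VarEta - sum(kap * rho))
        Jm <- batch$J[idx, Jobs, drop = FALSE]
      } else {
        s2 <- max(0, VarEta)
        rho <- numeric(0)
      }
      r_sc <- 1 / sqrt(1 + PROBIT_SCALE * s2)

      Zmat <- matrix(0, ng, nb)
      LJmat <- matrix(0, ng, nb)
      st <- vector("list", nb)
      for (b in seq_len(nb)) {
        Abar <- Arows
        if (length(S)) Abar[, S] <- rep(mS, each = ng)
        if (length(Bm)) Abar[, Bm] <- rep(cb[b, ], each = ng)
        ebar <- as.numeric(Abar %*% aA) + bY
        if (q) {
          T_ <- Abar %*% beta
          DJ <- Jm - T_ %*% Phi
          AJ <- DJ %*% Qx
          l_J <- -0.5 * rowSums(DJ * AJ) - 0.5 * logdetSx - 0.5 * q * log(2 * pi)
          m_eta <- ebar + as.numeric(DJ %*% rho)
        } else {
          T_ <- NULL
          DJ <- AJ <- NULL
          l_J <- numeric(ng)
          m_eta <- ebar
        }
        LJmat[, b] <- l_J + logw[b]
        Zmat[, b] <- m_eta * r_sc
        if (want_grad) {
          st[[b]] <- list(Abar = Abar, T_ = T_, DJ = DJ, AJ = AJ, m_eta = m_eta)
        }
      }
      if (mode == "joint") {
        Lmat <- LJmat + batch_y_term(Zmat, y)
        lse <- apply(Lmat, 1, max)
        ll <- lse + log(rowSums(exp(Lmat - lse)))
        out_ll[idx] <- ll + lpA
      } else {
        wmax <- apply(LJmat, 1, max)
        Wn <- exp(LJmat - wmax)
        Wn <- Wn / rowSums(Wn)
        out_pred[idx] <- rowSums(Wn * plogis(Zmat))
      }
      if (want_grad) {
        Pw <- exp(Lmat - ll)
        for (b in seq_len(nb)) {
          sb <- st[[b]]
          w <- w_rw * Pw[, b]
          p <- plogis(Zmat[, b])
          gmr <- (y - p) * r_sc
          gsr <- (y - p) * sb$m_eta * (-PROBIT_SCALE / 2) * r_sc^3
          gm <- w * gmr
          gs <- w * gsr
          sw <- sum(w)
          sgs <- sum(gs)
          sgm_Abar <- as.numeric(crossprod(sb$Abar, gm))
          grad$b_Y <- grad$b_Y + sum(gm)
          grad$alpha_A <- grad$alpha_A + sgm_Abar
          if (q) {
            AJ <- sb$AJ
            sA <- as.numeric(crossprod(AJ, gm))
            kapbar <- sA - 2 * sgs * rho
            SxBar <- 0.5 * (crossprod(AJ, w * AJ) - sw * Qx) -
              0.5 * (outer(rho, sA) + outer(sA, rho)) + sgs * outer(rho, rho)
            grad$E <- grad$E + sum(diag(SxBar))
            cbar <- as.numeric(Phi %*% kapbar)
            SffBar <- Phi %*% SxBar %*% t(Phi) +
              0.5 * (outer(aI, cbar) + outer(cbar, aI)) + sgs * outer(aI, aI)
            grad$beta <- grad$beta +
              crossprod(sb$Abar, (w * AJ) %*% t(Phi)) -
              outer(sgm_Abar, as.numeric(Phi %*% rho))
            grad$phi[, Jobs] <- grad$phi[, Jobs] +
              crossprod(sb$T_, w * AJ) + 2 * Sig %*% Phi %*% SxBar +
              outer(c_all, kapbar) - outer(as.numeric(crossprod(sb$T_, gm)), rho)
          } else {
            cbar <- numeric(d_f)
            SffBar <- sgs * outer(aI, aI)
          }
          grad$D <- grad$D + sum(diag(SffBar))
          gambar <- if (length(S)) {
            as.numeric(VR %*% cbar) + 2 * sgs * (vg + as.numeric(VR %*% aI))
          } else {
            numeric(0)
          }
          grad$alpha_I <- grad$alpha_I + as.numeric(Sig %*% cbar) +
            2 * sgs * c_all -
            (if (length(S)) as.numeric(crossprod(R, gambar)) else 0)
          if (length(S)) {
            grad$alpha_A[S] <- grad$alpha_A[S] + gambar
            gR <- 2 * (VR %*% SffBar) + outer(vg, cbar) +
              2 * sgs * outer(vg, aI) - outer(gambar, aI)
            grad$beta[S, ] <- grad$beta[S, ] + gR
          }
        }
      }
    }
  }

  if (want_grad) {
    # chain sigma^2 derivatives to the log-sigma parameterization
    g_lsI <- grad$D * 2 * D
    g_lsJ <- grad$E * 2 * E
    gvec <- c(
      as.numeric(grad$beta), as.numeric(grad$phi), grad$alpha_I,
      grad$alpha_A, grad$b_Y, g_lsI, g_lsJ
    )
  } else {
    gvec <- NULL
  }

  list(
    ll = out_ll,
    pred = if (mode == "predict") out_pred else NULL,
    grad = gvec, grad_F = grad_F
  )
}

# log Bernoulli factor implied by probit arguments Z and outcomes y,
# vectorized over an ng x nb matrix.
batch_y_term <- function(Zmat, y) {
  y * plogis(Zmat, log.p = TRUE) + (1 - y) * plogis(-Zmat, log.p = TRUE)
}
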