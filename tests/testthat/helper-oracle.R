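# Brute-force oracle for the change-point observer: computes the exact joint
# posterior P(r_T, xi_T | C_1:T) by enumerating every change-point
# configuration (segmentation) of the label sequence, summing over state
# assignments with a forward pass per segmentation. Independent of the
# filtering recursion it is used to check.
enumerate_joint_posterior <- function(labels01, spec) {
  T <- length(labels01)
  K <- spec$K
  P0 <- spec$P0
  pL <- 1 / (spec$L_max - spec$L_min + 1)   # P(L = l) on the support
  pGT <- function(rho) {                    # P(L > rho)
    if (rho < spec$L_min) 1
    else if (rho >= spec$L_max) 0
    else (spec$L_max - rho) * pL
  }
  seg_lik <- function(a, b) {
    nA <- sum(labels01[a:b])
    spec$states^nA * (1 - spec$states)^((b - a + 1) - nA)
  }
  out <- matrix(0, spec$L_max + 1, K + 1)
  recurse <- function(pos, w, m, struct) {
    rho <- T - pos + 1
    if (rho == 0) {
      # the last complete segment ended exactly at T: change after trial T
      if (m > 0) out[1, 2:(K + 1)] <<- out[1, 2:(K + 1)] + struct * w
    } else if (pGT(rho) > 0) {
      lik <- seg_lik(pos, T)                # current (incomplete) run
      if (m == 0) {
        out[rho + 1, 1] <<- out[rho + 1, 1] +
          struct * pGT(rho) * sum(P0[, 1] * lik)
      } else {
        f <- vapply(seq_len(K), function(k) sum(P0[, k + 1] * lik), 0)
        out[rho + 1, 2:(K + 1)] <<- out[rho + 1, 2:(K + 1)] +
          struct * pGT(rho) * (w * f)
      }
    }
    for (l in spec$L_min:spec$L_max) {      # a complete segment starts at pos
      if (pos + l - 1 > T) break
      lik <- seg_lik(pos, pos + l - 1)
      w2 <- if (m == 0) P0[, 1] * lik
            else vapply(seq_len(K), function(kp)
              sum(w * P0[kp, 2:(K + 1)]) * lik[kp], 0)
      recurse(pos + l, w2, m + 1, struct * pL)
    }
  }
  recurse(1, NULL, 0, 1)
  out / sum(out)
}

filter_joint_posterior <- function(labels01, spec) {
  b <- new_joint_belief(spec)
  for (c in labels01) b <- update_joint_belief(b, c)
  b$w
}
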