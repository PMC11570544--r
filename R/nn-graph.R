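# Minimal static computation-graph executor. A network is an ordered list of
# nodes (topological order); each node names its input nodes and, for
# parameterized ops, the entries of the shared parameter store it reads.
# Backward walks the list in reverse, accumulating gradients for every node
# output and every parameter.

nnNode <- function(name, op, inputs = character(), ...) {
  c(list(name = name, op = op, inputs = inputs), list(...))
}

# He-initialized conv weight matrix (k2*cin) x cout, row = (ci-1)*k2 + kk
convInit <- function(k, cin, cout) {
  matrix(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
         k * k * cin, cout)
}

# create the parameter/state entries a graph needs; returns list(params, state)
graphInitParams <- function(graph) {
  params <- list(); state <- list()
  for (nd in graph) {
    if (nd$op == "conv") {
      params[[paste0(nd$name, ".W")]] <- convInit(nd$k, nd$cin, nd$cout)
      params[[paste0(nd$name, ".b")]] <- numeric(nd$cout)
    } else if (nd$op == "bn") {
      params[[paste0(nd$name, ".gamma")]] <- rep(1, nd$C)
      params[[paste0(nd$name, ".beta")]] <- numeric(nd$C)
      state[[paste0(nd$name, ".rmean")]] <- numeric(nd$C)
      state[[paste0(nd$name, ".rvar")]] <- rep(1, nd$C)
    }
  }
  list(params = params, state = state)
}

#' @keywords internal
graphForward <- function(graph, params, state, inputs, training = FALSE,
                         bnMomentum = 0.1) {
  vals <- list(); caches <- list()
  for (nd in graph) {
    nm <- nd$name
    res <- switch(nd$op,
      input = {
        vals[[nm]] <- inputs[[nm]]; NULL
      },
      conv = {
        t <- vals[[nd$inputs]]
        vals[[nm]] <- convForward(t, params[[paste0(nm, ".W")]],
                                  params[[paste0(nm, ".b")]],
                                  nd$k, nd$s, nd$pad)
        NULL
      },
      bn = {
        t <- vals[[nd$inputs]]
        bc <- bnForward(t$x, params[[paste0(nm, ".gamma")]],
                        params[[paste0(nm, ".beta")]],
                        state[[paste0(nm, ".rmean")]],
                        state[[paste0(nm, ".rvar")]], training,
                        momentum = bnMomentum)
        state[[paste0(nm, ".rmean")]] <- bc$rmean
        state[[paste0(nm, ".rvar")]] <- bc$rvar
        vals[[nm]] <- nnTensor(bc$y, t$N, t$H, t$W)
        caches[[nm]] <- bc
        NULL
      },
      relu = {
        t <- vals[[nd$inputs]]
        vals[[nm]] <- nnTensor(pmax(t$x, 0), t$N, t$H, t$W)
        NULL
      },
      sigmoid = {
        t <- vals[[nd$inputs]]
        vals[[nm]] <- nnTensor(sigmoidStable(t$x), t$N, t$H, t$W)
        NULL
      },
      resize = {
        t <- vals[[nd$inputs[1]]]
        ref <- vals[[nd$inputs[2]]]
        vals[[nm]] <- resizeForward(t, ref$H, ref$W)
        NULL
      },
      concat = {
        ts <- vals[nd$inputs]
        vals[[nm]] <- nnTensor(do.call(cbind, lapply(ts, `[[`, "x")),
                               ts[[1]]$N, ts[[1]]$H, ts[[1]]$W)
        NULL
      },
      add = {
        a <- vals[[nd$inputs[1]]]; b <- vals[[nd$inputs[2]]]
        vals[[nm]] <- nnTensor(a$x + b$x, a$N, a$H, a$W)
        NULL
      },
      mul = {
        a <- vals[[nd$inputs[1]]]; b <- vals[[nd$inputs[2]]]
        # b may have a single channel broadcast over a's channels
        bx <- if (b$C == a$C) b$x else b$x[, rep(1L, a$C), drop = FALSE]
        vals[[nm]] <- nnTensor(a$x * bx, a$N, a$H, a$W)
        NULL
      },
      chanpool = {
        t <- vals[[nd$inputs]]
        cp <- chanPoolForward(t$x)
        vals[[nm]] <- nnTensor(cp$y, t$N, t$H, t$W)
        caches[[nm]] <- cp
        NULL
      },
      stop("unknown op: ", nd$op)
    )
  }
  list(vals = vals, state = state, caches = caches)
}

#' @keywords internal
graphBackward <- function(graph, params, fwd, dOut) {
  vals <- fwd$vals; caches <- fwd$caches
  dvals <- list(); dparams <- list()
  for (nm in names(dOut)) dvals[[nm]] <- dOut[[nm]]
  acc <- function(nm, g) {
    if (is.null(dvals[[nm]])) dvals[[nm]] <<- g else dvals[[nm]] <<- dvals[[nm]] + g
  }
  for (nd in rev(graph)) {
    nm <- nd$name
    dY <- dvals[[nm]]
    if (is.null(dY) || nd$op == "input") next
    switch(nd$op,
      conv = {
        t <- vals[[nd$inputs]]
        bk <- convBackward(t, dY, params[[paste0(nm, ".W")]], nd$k, nd$s, nd$pad)
        dparams[[paste0(nm, ".W")]] <- bk$dW
        dparams[[paste0(nm, ".b")]] <- bk$db
        acc(nd$inputs, bk$dX)
      },
      bn = {
        bk <- bnBackward(dY, caches[[nm]], params[[paste0(nm, ".gamma")]])
        dparams[[paste0(nm, ".gamma")]] <- bk$dgamma
        dparams[[paste0(nm, ".beta")]] <- bk$dbeta
        acc(nd$inputs, bk$dX)
      },
      relu = {
        t <- vals[[nd$inputs]]
        acc(nd$inputs, dY * (t$x > 0))
      },
      sigmoid = {
        y <- vals[[nm]]$x
        acc(nd$inputs, dY * y * (1 - y))
      },
      resize = {
        t <- vals[[nd$inputs[1]]]; ref <- vals[[nd$inputs[2]]]
        acc(nd$inputs[1], resizeBackward(dY, t, ref$H, ref$W))
      },
      concat = {
        off <- 0L
        for (inp in nd$inputs) {
          C <- vals[[inp]]$C
          acc(inp, dY[, off + seq_len(C), drop = FALSE])
          off <- off + C
        }
      },
      add = {
        acc(nd$inputs[1], dY)
        acc(nd$inputs[2], dY)
      },
      mul = {
        a <- vals[[nd$inputs[1]]]; b <- vals[[nd$inputs[2]]]
        if (b$C == a$C) {
          acc(nd$inputs[1], dY * b$x)
          acc(nd$inputs[2], dY * a$x)
        } else {
          acc(nd$inputs[1], dY * b$x[, rep(1L, a$C), drop = FALSE])
          acc(nd$inputs[2], matrix(rowSums(dY * a$x), ncol = 1))
        }
      },
      chanpool = {
        t <- vals[[nd$inputs]]
        acc(nd$inputs, chanPoolBackward(dY, t$x, caches[[nm]]$amax))
      }
    )
  }
  list(dparams = dparams, dvals = dvals)
}
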