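# edn — error-driven neurogenesis networks

`edn` is an R implementation of a biologically inspired one-shot, online
learning algorithm. Instead of tuning the weights of a fixed architecture
by gradient descent, the network *grows*: it starts empty, and whenever
its prediction error exceeds a threshold it creates a new neuron that
stores the current input on triangle-kernel synapses and wires itself to
the outputs with weights proportional to the error. Stored parameters are
never modified afterwards, so a single presentation of a sample is enough
to memorize and immediately use it, and new learning cannot overwrite old
knowledge.

The same mechanism covers three paradigms:

* **classification** — the error is `one-hot(label) − softmax(outputs)`;
  surprise-driven input selection stores only the inputs that deviate from
  the class's learned expectation;
* **regression** — targets are coded by a real/inverse output pair whose
  ratio `r/(r+i)` pins a position on the target scale independently of
  activity level;
* **reinforcement learning** — on failure, the last `m` timesteps are
  inhibited with linearly fading weight (−1 for the newest step), neurons
  accumulate a low-pass reward `R ← τR + (1−τ) r aₙ`, and a size cap prunes
  the lowest-reward neuron. A self-contained cart-pole environment is
  included.

The forward pass, for input vector `x`:

```
synapse:  k(x)  = max(0, 1 − |v − x| / s)        triangle kernel, center v, spread s
neuron:   aₙ    = mean over stored afferents of k(xᵢ)
output:   a_y   = Σ over neurons of w · k(aₙ)     efferent kernel centered at 1
```

The efferent kernel silences every neuron with `aₙ ≤ 1 − s`, so outputs
only hear from neurons closely matching their stored pattern. If all
outputs are exactly zero the network **abstains** (`NA`) instead of
guessing.

Because everything the model knows sits in plain synapse parameters, the
package can also read the model back out: per-class expectation images
(`class_expectation_image()`), signed receptive fields
(`receptive_field()`), and 2-D decision-boundary rasters
(`decision_grid()`).

## Worked example

```r
library(edn)
set.seed(1)

blobs <- make_blobs(seed = 1)                  # 3 Gaussian classes, 60 points
norm  <- fit_normalizer(blobs$x)
x     <- apply_normalizer(norm, blobs$x)

net <- edn_network(n_inputs = 2, n_outputs = 3, spread = 0.4,
                   error_threshold = 0.1)
fit <- train_classification(net, x, blobs$y)   # one online epoch
fit$network
#> <edn_network> 2 inputs -> 3 outputs | s=0.4 E_th=0.1 s_th=0.05
#>   46 neurons, 92 afferent synapses

test  <- make_blobs(seed = 2)
preds <- classify(fit$network, apply_normalizer(norm, test$x))
mean(preds == test$y)
#> [1] 1
```

Sixty presentations created 46 neurons (errors below the 0.1 threshold
create nothing) and the grown network classifies a fresh sample of the
same blobs perfectly. The training log records the prediction *before*
each update, the error magnitude, and the growth trace:

```r
tail(fit$log, 3)
#>    step prediction  max_error neurons synapses
#> 58   58          2 0.07109087      45       90
#> 59   59          3 0.16675916      46       92
#> 60   60          3 0.08856282      46       92
```

Regression uses the real/inverse codec; a real magnitude of 26 and an
inverse magnitude of 14 decode to position 26/(26+14) on a 0–1 scale:

```r
decode_outputs(26, 14, regression_scale(0, 1))
#> [1] 0.65
```

Reinforcement learning on the built-in cart-pole, with a 350-neuron cap
and reward-based pruning (solved = mean balance over the last 100 trials
above 475 of the 500-step maximum):

```r
run <- run_cartpole_training(spread = 0.6, memory = 10, max_size = 350,
                             seed = 3)
run$trials_to_solve
#> [1] 119
tail(run$neurons, 1)
#> [1] 246
```

A command-line front end over the same functions lives at
`inst/cli/edn.R` (`train-classify`, `train-regress`, `cartpole`,
`inspect`, `synth`).

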