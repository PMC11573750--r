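---
title: "Methods: three-party secure RKN inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-party secure RKN inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(secureRKN)
```

## The problem and the model

Protein fold recognition asks whether a query amino-acid sequence adopts a
structural fold, by scoring it against models trained on sequences of known
structure. A recurrent kernel network (RKN) scores a sequence $x$ against $q$
learned anchor points (motif templates of length $k$): at position $t$ and
level $j$ the per-anchor similarity is

$$ b_j[t]_i = \exp\big(\alpha\,(\langle z_{j,\cdot,i}, x_t\rangle - 1)\big), $$

with $x_t$ the one-hot encoding of residue $t$ and $z_{j,\cdot,i}$ the unit-norm
$j$-th character of anchor $i$. The running $k$-mer embedding follows the
gap-decayed recurrence

$$ c_j[t] = \lambda\, c_j[t-1] + b_j[t] \odot c_{j-1}[t-1],
   \qquad c_0 \equiv 1,\; c_j[0] = 0, $$

and after the last position the level-$k$ embedding is whitened by the inverse
square root of the anchor gram matrix, $\psi = K_{ZZ}^{-1/2}\, c_k[|x|]$, and
scored by a linear classifier, $\hat y = \langle w, \psi\rangle + \beta$.
`rkn_forward()` implements this in double precision and is the oracle
everything else is checked against. Only the level-$k$ embedding feeds the
classifier; multi-level concatenation and the gap-penalized variants of the
original RKN are out of scope here, and the single bias $\beta$ is the only
bias term the outsourced parameter set contains.

In the service setting, neither the sequence owner nor the model owner reveals
their input: both additively secret-share their data to two proxies
(P0, P1), which evaluate the circuit with the assistance of a helper (P2)
that deals correlated randomness and computes on masked values. At the end
the proxies hold shares of the prediction; only the data owner, receiving
both, can reconstruct it.

## Number system

All secrets live in $\mathbb{Z}_L$ with $L = 2^n$ ($n = 64$ by default),
intermediately in $\mathbb{Z}_K$ with $K = 2^{n-1}$, and the bits used by the
private comparison are shared over the prime field $\mathbb{Z}_{67}$
($67 > n + 2$, which is exactly what bounds the comparison intermediates away
from wrapping). Reals are fixed-point: an $n$-bit two's-complement word with
$f = 20$ fractional bits, so the representable range is $|v| < 2^{43}$ and the
resolution $2^{-20} \approx 9.5\times10^{-7}$. Encoding rounds half away from
zero; any consistent rule works at the accuracy targets of this package. The
ring width is configurable ($n \in \{8,16,32,64\}$) so that every protocol is
*exhaustively* testable at $n = 8$; small rings default to $f = 0$.

Ring words are stored bit-cast into R doubles (the `bit64` storage technique)
and all ring arithmetic runs in C++ on `uint64_t`; R never touches the values
arithmetically.

## Protocol choices and their numerics

**Multiplication and matrix products** use helper-dealt Beaver triples; the
only values that cross between proxies are the maskings $x-a$, $y-b$. Matrix
products use one matrix triple per call and truncate once per output entry
after accumulation.

**Truncation.** After a fixed-point product the $2f$-scaled result is
truncated locally: P0 shifts its share, P1 negates-shifts-negates. This
reconstructs to $\lfloor v/2^f \rfloor$ plus a Bernoulli carry with success
probability equal to the dropped fraction — stochastic rounding, unbiased in
expectation. Two refinements were settled empirically:

* a deterministic rounding offset (adding $2^{f-1}$ on one share before
  shifting) was tried and rejected: it *adds* a systematic $+0.5$ ULP bias per
  product, which compounds visibly through the exponential's 31 tree
  products;
* plain local truncation is off by the full modulus whenever P0's uniform
  share lands within $|v\cdot 2^f|$ of the ring boundary (probability
  $\approx 2^{-23}$ per element — but a $q{=}128$, $k{=}10$ inference performs
  millions of truncations, so blowups *will* happen at scale). P0 therefore
  flags danger-zone elements — a decision based only on its own share, which
  is uniform and independent of the secret, hence leak-free — and both proxies
  shift flagged elements by the public constant $2^{n-10}$ before shifting.
  The off-by-one error contract then holds with certainty, for pre-truncation
  magnitudes below $2^{n-11}$ (decoded products below $2^{n-11-2f} = 2^{13}$
  at the defaults).

**Modulus conversion (MOC)** lifts shares from $\mathbb{Z}_K$ to
$\mathbb{Z}_L$: the helper deals a random $r$ (additively over $K$, bitwise
over $\mathbb{Z}_{67}$, plus Boolean shares of its sharing's wrap); the
proxies open $y = x + r \bmod K$, resolve the wrap of $x+r$ with one private
compare ($r > y$), and correct by $K$ per Boolean share — sound because
$2K \equiv 0 \pmod L$, so a doubly-applied correction cancels.

**Private compare** follows the SecureNN construction over
$\mathbb{Z}_{67}$: per-bit masked differences with prefix sums of XOR terms,
scaled by common random non-zero field elements and permuted per element; the
helper only learns whether some position is zero, masked by a common random
bit it never sees. Because compared values are below $K$ but carried on $n$
bits, the textbook edge case (the complement test overflowing at $r = 2^n-1$)
cannot occur and is not implemented; the $n = 8$ tests cover all $(x, r)$
pairs exhaustively.

**MSB** splits off the low $n-1$ bits share-locally, lifts them back via MOC,
subtracts to get $z \in \{0, K\}$, and has the helper map the two candidates
$z_0, z_0+K$ — sent in an order decided by a common tape bit the helper does
not know — to fresh shares of 0/1.

**MUX** computes $z = x - b(x-y)$ with the two cross-party products
outsourced through a randomized encoding: P0 sends $M_2 = \langle b\rangle_0 +
r_0$ and $M_3 = (\langle x\rangle_0-\langle y\rangle_0) + r_3$, P1 sends
$M_5 = (\langle x\rangle_1-\langle y\rangle_1) + r_1$ and $M_6 = \langle
b\rangle_1 + r_2$; the helper returns fresh shares of $M_2M_5 + M_3M_6$ and
the proxies cancel the tape terms locally. Selector bits are raw ring values
0/1 (the output format of MSB/CMP), so MUX needs no truncation.

**Exponential.** $\mathrm{base}^x$ for a shared fixed-point power $x$ is
computed exactly (up to fixed-point resolution) in the square-and-multiply
style: one MSB for the sign; one vectorized MUX selecting $\{x,$ table
$C_p\}$ vs $\{-x,$ table $C_n\}$ where $C_p[i] = b^{2^{i-f}}$ and
$C_n[i] = b^{-2^{i-f}}$ (one proxy holds the tables in plaintext, the other
holds zeros — a valid sharing); one vectorized MSB over left-shifted copies of
$|x|$ exposing every covered bit; one vectorized MUX choosing
contribution-or-1 per bit; and a binary tree of vectorized multiplications.
The covered window keeps only representable contributions: for base $e$ at
$n=64, f=20$ that is integer weights $2^0..2^4$ plus all 20 fractional
weights — 25 entries, padded with encoded 1s to 32, hence
$\log_2 32 = 5$ multiplication levels, and a valid domain $|x| \lesssim 30$
(bounded by representability of the result; this cannot be checked privately
and is a documented caller contract). The transcript of one call shows
exactly 2 MSB, 2 MUX and 5 MUL invocations.

A quantization fact worth stating: at $f = 20$, $e^{-10}$ has only ~48
representable quanta, so *no* method can reach $10^{-4}$ relative error
there; symmetrically, $10^{-4}$ absolute is unreachable at $e^{10}$. The
accuracy the implementation achieves — and the tests assert — is "within a
few quanta of the best representable value" across $[-10, 10]$, which implies
$10^{-4}$ accuracy in the mixed sense (relative above 1, absolute below).

## The private circuit

Per position: one matrix product for the $k\cdot q$ anchor dot products
(inner dimension = alphabet size, one truncation); a local affine step
$\alpha(\cdot - 1)$ fused into a single truncation; one vectorized EXP; and
the recurrence update $\lambda c_j + b_j \odot c_{j-1}$, computed as one
batched Beaver product plus a local scalar product truncated *together*
(fusing the plaintext-scalar scaling into the product's truncation halves the
rounding noise injected per step; the unfused variant is algebraically
identical). Sequence positions are strictly serial (the recurrence demands
it); all per-position work is batched across $j$ and $q$, which is why
invocation *counts* grow only with sequence length while communicated *bytes*
grow with each of $q$, $k$ and $|x|$ — the package's portable proxy for the
linear execution-time scaling of the deployed service.

Intermediate values stay in fixed point over $L$ throughout; $\alpha$,
$\lambda$ and the exponential base remain plaintext at the proxies. The EXP
power $\alpha(\langle z, x_t\rangle - 1)$ lies in $[-2\alpha, 0]$ by the
unit-norm anchor invariant, and the model-outsourcing step validates
$2\alpha$ against the EXP coverage window.

## Party runtime and transports

The three parties are simulated in one process: party state (common tape for
P0/P1, an independent dealing stream for P2, per-party streams) is explicit,
and every value that crosses a party boundary goes through a message router
that counts invocations, messages and bytes, and can retain everything the
helper sees (the privacy smoke tests run chi-square uniformity checks on
those payloads at $n = 8$). Two transports exist: `inproc` hands payloads
over directly; `socket` frames each payload (4-byte little-endian length
prefix, little-endian 64-bit words) through a real localhost TCP connection.
Both produce bit-identical transcripts and prediction shares for equal seeds.
A multi-process deployment harness is deliberately not provided — the
simulator is what the correctness and scaling claims need; the socket
transport exercises the wire format. Every random draw comes from a seeded
splitmix64 stream, so a run is fully reproducible from
(common, P0, P1, P2) seeds. How external users authenticate to the proxies
is a deployment concern and out of scope.

## Synthetic data: what it emulates, what it does not

`generate_rkn_model()` draws anchor characters standard normal and normalizes
rows to unit norm; classifier weights and bias are standard normal;
$\alpha = 0.6$, $\lambda = 0.5$ by default. The gram matrix whose inverse
square root whitens the embedding is the *kernel* gram of the anchor points,
$\exp(\alpha(\langle z_i, z_j\rangle - k))$ — strictly positive definite for
distinct anchors — inverted by eigendecomposition with a $10^{-6}$ eigenvalue
floor. A linear gram of flattened anchors was rejected: for $q > 20k$ it is
rank-deficient, and with the eigenvalue floor its inverse square root has
entries $\sim 10^3$ that amplify fixed-point noise far beyond any meaningful
tolerance. Sequences are i.i.d. uniform over the 20-letter alphabet.

What a green test on this generator establishes: that the private circuit
tracks the plaintext circuit to fixed-point accuracy on models with the right
shapes, scales and invariants. What it does not establish: classification
accuracy of trained models (no training here), biological realism of the
sequences, or the absolute error one would observe on a trained model —
trained classifiers have $O(1)$ scores, whereas random $N(0,1)$ weights at
$q = 128$ give scores of $O(10)$ whose absolute (not relative) error is
correspondingly larger.

## Known limitations

* Training/fine-tuning, max-pooling variants and multi-class outputs are out
  of scope; the gram inverse square root is computed in plaintext by the
  model owner.
* Security is semi-honest with an honest majority, argued structurally
  (party-local state, masked messages) and tested statistically; this is a
  research simulator, not a hardened deployment.
* Non-standard residues (B, Z, X, U, O) are rejected by default; an opt-in
  maps them to all-zero rows.
* The absolute private-vs-plaintext gap grows with the magnitude of the
  score: each recurrence step injects ~1 ULP of stochastic rounding noise
  per entry, and the final $\langle w, \psi\rangle$ sums $q$ such entries.
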