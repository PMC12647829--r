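#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Time-driven conductance-based LIF integration.
//
// Per step (dt): receptor conductances decay exponentially, pending synaptic
// increments (delayed spikes) are applied, then the membrane is advanced with
// the exponential-Euler closed form that treats each conductance as constant
// within the step at its exact step average g * (tau/dt)(1 - e^(-dt/tau)).
// Using the step average rather than the step-start value makes the total
// charge delivered by one synaptic event independent of dt (the integral of
// the decaying exponential is reproduced exactly), which is what gives the
// integrator its step-size convergence. Threshold crossing emits a spike,
// resets the membrane and enforces an absolute refractory period during
// which V is clamped at Vreset (conductances keep evolving).
//
// All synapse lists are CSR-indexed by presynaptic neuron: edges of neuron i
// live in [ptr[i], ptr[i+1]). External (mossy fiber) input arrives as a
// pre-generated spike list (source id, step), fanned out through its own CSR.
// Delays are integer step counts (>= 1 for recurrent edges).

// [[Rcpp::export]]
List lif_simulate_cpp(NumericVector Cm, NumericVector grest,
                      NumericVector Erest, NumericVector Eampa,
                      NumericVector Egaba, NumericVector Vth,
                      NumericVector Vreset,
                      NumericVector decayA, NumericVector decayG,
                      IntegerVector refSteps,
                      IntegerVector synPtr, IntegerVector synTarget,
                      IntegerVector synReceptor, IntegerVector synDelay,
                      NumericVector synWeight,
                      IntegerVector extSpikeSrc, IntegerVector extSpikeStep,
                      IntegerVector extPtr, IntegerVector extTarget,
                      IntegerVector extReceptor, IntegerVector extDelay,
                      NumericVector extWeight,
                      int nSteps, double dt,
                      IntegerVector recordIds) {
  const int n = Cm.size();
  std::vector<double> V(n), gA(n, 0.0), gG(n, 0.0);
  std::vector<int> refUntil(n, -1);
  for (int i = 0; i < n; ++i) V[i] = Erest[i];

  int maxDelay = 1;
  for (int k = 0; k < synDelay.size(); ++k)
    if (synDelay[k] > maxDelay) maxDelay = synDelay[k];
  for (int k = 0; k < extDelay.size(); ++k)
    if (extDelay[k] > maxDelay) maxDelay = extDelay[k];
  const int ring = maxDelay + 1;

  // pending conductance increments, one bucket per future step
  std::vector<std::vector<int> > pendTarget(ring), pendReceptor(ring);
  std::vector<std::vector<double> > pendWeight(ring);

  std::vector<int> spkId;
  std::vector<double> spkT;
  spkId.reserve(1 << 16);
  spkT.reserve(1 << 16);

  const int nRec = recordIds.size();
  NumericMatrix Vrec(nRec > 0 ? nSteps : 0, nRec);

  const int nExt = extSpikeStep.size();
  int extPos = 0; // extSpikeStep assumed sorted ascending

  // passive-decay factor toward rest used when synaptic conductances have
  // decayed to nothing (pure leak; avoids the per-step exp for idle cells)
  std::vector<double> krest(n), avgA(n), avgG(n);
  for (int i = 0; i < n; ++i) {
    krest[i] = std::exp(-grest[i] * dt / Cm[i]);
    // step-average factor (tau/dt)(1 - e^(-dt/tau)) from the decay constant
    avgA[i] = (1.0 - decayA[i]) / (-std::log(decayA[i]));
    avgG[i] = (1.0 - decayG[i]) / (-std::log(decayG[i]));
  }
  const double gtol = 1e-10; // nS; far below any synaptic increment

  for (int s = 0; s < nSteps; ++s) {
    // 1. conductance decay
    for (int i = 0; i < n; ++i) {
      gA[i] *= decayA[i];
      gG[i] *= decayG[i];
    }
    // 2. enqueue external spikes scheduled at this step
    while (extPos < nExt && extSpikeStep[extPos] == s) {
      const int src = extSpikeSrc[extPos];
      for (int k = extPtr[src]; k < extPtr[src + 1]; ++k) {
        const int slot = (s + extDelay[k]) % ring;
        pendTarget[slot].push_back(extTarget[k]);
        pendReceptor[slot].push_back(extReceptor[k]);
        pendWeight[slot].push_back(extWeight[k]);
      }
      ++extPos;
    }
    // 3. deliver pending increments due now
    {
      const int slot = s % ring;
      std::vector<int> &tg = pendTarget[slot];
      std::vector<int> &rc = pendReceptor[slot];
      std::vector<double> &wt = pendWeight[slot];
      for (size_t k = 0; k < tg.size(); ++k) {
        if (rc[k] == 0) gA[tg[k]] += wt[k]; else gG[tg[k]] += wt[k];
      }
      tg.clear(); rc.clear(); wt.clear();
    }
    // 4. membrane update, threshold, spike propagation
    for (int i = 0; i < n; ++i) {
      if (s < refUntil[i]) {
        V[i] = Vreset[i];
        continue;
      }
      if (gA[i] < gtol && gG[i] < gtol) {
        gA[i] = 0.0; gG[i] = 0.0;
        V[i] = Erest[i] + (V[i] - Erest[i]) * krest[i];
        continue; // Erest < Vth by construction: no spike possible
      }
      const double ga = gA[i] * avgA[i], gg = gG[i] * avgG[i];
      const double gtot = ga + gg + grest[i];
      const double vinf =
        (ga * Eampa[i] + gg * Egaba[i] + grest[i] * Erest[i]) / gtot;
      V[i] = vinf + (V[i] - vinf) * std::exp(-gtot * dt / Cm[i]);
      if (V[i] >= Vth[i]) {
        spkId.push_back(i);
        spkT.push_back((s + 1) * dt);
        V[i] = Vreset[i];
        refUntil[i] = s + 1 + refSteps[i];
        for (int k = synPtr[i]; k < synPtr[i + 1]; ++k) {
          const int slot = (s + synDelay[k]) % ring;
          pendTarget[slot].push_back(synTarget[k]);
          pendReceptor[slot].push_back(synReceptor[k]);
          pendWeight[slot].push_back(synWeight[k]);
        }
      }
      if (!std::isfinite(V[i]) || V[i] > 100.0 || V[i] < -200.0)
        stop("membrane potential diverged at step %d, neuron %d", s, i + 1);
    }
    if (nRec > 0)
      for (int r = 0; r < nRec; ++r) Vrec(s, r) = V[recordIds[r]];
  }

  return List::create(_["id"] = wrap(spkId), _["time"] = wrap(spkT),
                      _["V"] = Vrec);
}

// Spike counts per (neuron, window) for fixed-width contiguous windows.
// [[Rcpp::export]]
IntegerMatrix window_counts_cpp(IntegerVector id, NumericVector time,
                                int nNeurons, double t0, double winMs,
                                int nWindows) {
  IntegerMatrix out(nNeurons, nWindows);
  for (int k = 0; k < id.size(); ++k) {
    const double rel = time[k] - t0;
    if (rel < 0) continue;
    const int w = (int)std::floor(rel / winMs);
    if (w >= nWindows) continue;
    ++out(id[k], w);
  }
  return out;
}
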