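#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Series combination of the conductivities of two half-segments over the
// distance h between segment centres: (h/2)/s1 + (h/2)/s2 in resistance form,
// i.e. 2*s1*s2/(s1+s2).  Returns 0 when either side is blocked.
static inline double harm2(double s1, double s2) {
    if (s1 <= 0.0 || s2 <= 0.0) return 0.0;
    return 2.0 * s1 * s2 / (s1 + s2);
}

// Explicit forward-Euler integration of the electrodiffusive cable system.
//
// State: number densities n[k][i] (1/m^3) on N interior segments; the
// potential is derived every step from the net charge and the membrane
// capacitance, phi_i = a_i/(2 c_m) * e * (sum_k z_k n_ki - n0_i).
//
// Interfaces m = 0..N sit between segments (m-1, m); segments -1 and N are
// ghosts.  Synaptic end (m = 0): zero potential gradient, zero flux for all
// species except the injected one, whose Neumann influx is applied as the
// equivalent per-step source I/(z e) particles per second into segment 0.
// Dendritic end (m = N): ghost concentrations held at rest, ghost potential
// clamped to the phase value (or mirrored when closed_right, a test mode
// with fully reflecting boundaries).
//
// [[Rcpp::export]]
List simulate_core(NumericMatrix n_init,      // K x N number densities
                   NumericVector n0,          // N, immobile background (1/m^3)
                   NumericVector a,           // N segment radii (m)
                   double h,                  // segment length (m)
                   IntegerVector z,           // K valences
                   NumericVector D,           // K diffusion constants (m^2/s)
                   NumericVector n_ghost,     // K dendritic ghost densities
                   double e, double kB, double T, double cm,
                   int influx_species,        // 0-based index, -1 = none
                   NumericVector phase_steps, // steps per phase
                   NumericVector phase_I,     // injected current per phase (A)
                   NumericVector phase_clamp, // dendritic ghost potential (V)
                   int record_stride,
                   double dt,
                   bool closed_right,
                   bool freeze_sigma,         // drift conductivities at t=0
                   bool no_diffusion,         // drop interior diffusion fluxes
                   double guard_phi)          // |phi| abort threshold (V)
{
    const int K = n_init.nrow(), N = n_init.ncol();
    const int P = phase_steps.size();

    long long total_steps = 0;
    std::vector<long long> pstep(P);
    for (int p = 0; p < P; ++p) {
        pstep[p] = (long long) phase_steps[p];
        total_steps += pstep[p];
    }

    std::vector<double> n(K * N), dn(K * N);
    for (int k = 0; k < K; ++k)
        for (int i = 0; i < N; ++i) n[k * N + i] = n_init(k, i);

    std::vector<double> phi(N), sig_e(K * N), sig_e0(K * N);
    std::vector<double> ze(K), ce(K), cd(K);
    for (int k = 0; k < K; ++k) {
        ze[k] = z[k] * e;
        // sigma_e,k = a^2 D_k e^2 z_k^2 n_k / (kB T), per unit n
        ce[k] = D[k] * e * e * double(z[k]) * double(z[k]) / (kB * T);
        cd[k] = D[k]; // sigma_d,k = a^2 D_k
    }
    std::vector<double> a2(N), inv_a2(N);
    for (int i = 0; i < N; ++i) { a2[i] = a[i] * a[i]; inv_a2[i] = 1.0 / a2[i]; }
    const double aR2 = a2[N - 1];            // dendritic ghost radius
    std::vector<double> sig_e_ghost(K);      // dendritic ghost, rest state
    for (int k = 0; k < K; ++k) sig_e_ghost[k] = aR2 * ce[k] * n_ghost[k];

    // diffusion interface conductivities are time-invariant: a^2 D_k,
    // harmonically averaged; index m = 1..N-1 interior, m = N dendritic
    std::vector<double> sd_int(K * (N + 1), 0.0);
    for (int k = 0; k < K; ++k) {
        for (int m = 1; m < N; ++m)
            sd_int[k * (N + 1) + m] = harm2(a2[m - 1] * cd[k], a2[m] * cd[k]);
        sd_int[k * (N + 1) + N] = harm2(a2[N - 1] * cd[k], aR2 * cd[k]);
    }

    // frozen (t = 0) drift conductivities, used when freeze_sigma
    for (int k = 0; k < K; ++k)
        for (int i = 0; i < N; ++i)
            sig_e0[k * N + i] = a2[i] * ce[k] * n_init(k, i);

    const double inv_h2 = 1.0 / (h * h);
    const double phi_fac = e / (2.0 * cm);

    // recording buffers
    long long n_rec_max = total_steps / record_stride + 3;
    NumericVector times((R_xlen_t) n_rec_max);
    NumericMatrix phi_rec((R_xlen_t) n_rec_max, N);
    List conc_rec(K);
    std::vector<NumericMatrix> crec;
    for (int k = 0; k < K; ++k) {
        NumericMatrix m((R_xlen_t) n_rec_max, N);
        conc_rec[k] = m;
        crec.push_back(m);
    }
    long long n_rec = 0;
    bool unstable = false;
    double t_unstable = NA_REAL;

    long long step = 0;
    int phase = 0;
    long long phase_left = (P > 0) ? pstep[0] : 0;

    auto compute_phi = [&](void) {
        for (int i = 0; i < N; ++i) {
            double q = -n0[i];
            for (int k = 0; k < K; ++k) q += double(z[k]) * n[k * N + i];
            phi[i] = a[i] * phi_fac * q;
        }
    };

    auto record = [&](double tnow) -> bool {
        compute_phi();
        for (int i = 0; i < N; ++i) {
            phi_rec(n_rec, i) = phi[i];
            for (int k = 0; k < K; ++k) {
                const double v = n[k * N + i];
                crec[k](n_rec, i) = v;
                // negative or non-finite concentrations mean blow-up even
                // for neutral species whose potential stays flat
                if (!(v >= 0.0)) unstable = true;
            }
            if (!std::isfinite(phi[i]) || std::fabs(phi[i]) > guard_phi)
                unstable = true;
        }
        times[n_rec] = tnow;
        ++n_rec;
        if (unstable) t_unstable = tnow;
        return unstable;
    };

    record(0.0);

    while (step < total_steps && !unstable) {
        while (phase_left == 0 && phase < P - 1) {
            ++phase;
            phase_left = pstep[phase];
        }
        const double I_in = phase_I[phase];
        const double phi_R = phase_clamp[phase];

        compute_phi();
        if (!freeze_sigma) {
            for (int k = 0; k < K; ++k) {
                const double c = ce[k];
                for (int i = 0; i < N; ++i)
                    sig_e[k * N + i] = a2[i] * c * n[k * N + i];
            }
        }
        const double* se = freeze_sigma ? sig_e0.data() : sig_e.data();

        for (int k = 0; k < K; ++k) {
            const double* nk = &n[k * N];
            const double* sek = se + k * N;
            const double* sdk = &sd_int[k * (N + 1)];
            double* dnk = &dn[k * N];
            const double inv_ze = (z[k] != 0) ? 1.0 / ze[k] : 0.0;
            const bool charged = (z[k] != 0);

            for (int i = 0; i < N; ++i) dnk[i] = 0.0;

            // interior interfaces m = 1..N-1 between segments m-1, m
            for (int m = 1; m < N; ++m) {
                double flux = 0.0; // divergence contribution, sign per segment
                if (charged)
                    flux = inv_ze * harm2(sek[m - 1], sek[m]) *
                           (phi[m] - phi[m - 1]);
                if (!no_diffusion)
                    flux += sdk[m] * (nk[m] - nk[m - 1]);
                flux *= inv_h2;
                dnk[m - 1] += flux * inv_a2[m - 1];
                dnk[m]     -= flux * inv_a2[m];
            }

            // dendritic boundary interface m = N
            if (!closed_right) {
                double flux = 0.0;
                if (charged)
                    flux = inv_ze * harm2(sek[N - 1], sig_e_ghost[k]) *
                           (phi_R - phi[N - 1]);
                if (!no_diffusion)
                    flux += sdk[N] * (n_ghost[k] - nk[N - 1]);
                dnk[N - 1] += flux * inv_h2 * inv_a2[N - 1];
            }
            // (closed_right: mirror ghost => zero flux, nothing to add)

            // synaptic boundary: zero potential gradient and zero flux for
            // all species; the injected species receives I/(z e) particles
            // per second distributed over the first segment volume
            if (k == influx_species && I_in != 0.0) {
                dnk[0] += I_in / (ze[k] * M_PI * a2[0] * h);
            }
        }

        for (int k = 0; k < K; ++k)
            for (int i = 0; i < N; ++i) n[k * N + i] += dt * dn[k * N + i];

        ++step;
        --phase_left;

        if (step % record_stride == 0 || step == total_steps) {
            if (record(step * dt)) break;
        }
    }

    // trim buffers
    NumericVector t_out((R_xlen_t) n_rec);
    NumericMatrix phi_out((R_xlen_t) n_rec, N);
    List conc_out(K);
    for (long long s = 0; s < n_rec; ++s) {
        t_out[s] = times[s];
        for (int i = 0; i < N; ++i) phi_out(s, i) = phi_rec(s, i);
    }
    for (int k = 0; k < K; ++k) {
        NumericMatrix m((R_xlen_t) n_rec, N);
        for (long long s = 0; s < n_rec; ++s)
            for (int i = 0; i < N; ++i) m(s, i) = crec[k](s, i);
        conc_out[k] = m;
    }
    NumericMatrix n_final(K, N);
    for (int k = 0; k < K; ++k)
        for (int i = 0; i < N; ++i) n_final(k, i) = n[k * N + i];

    return List::create(
        _["times"] = t_out,
        _["phi"] = phi_out,
        _["conc"] = conc_out,
        _["n_final"] = n_final,
        _["status"] = unstable ? "unstable" : "stable",
        _["t_unstable"] = t_unstable,
        _["steps_done"] = (double) step);
}
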