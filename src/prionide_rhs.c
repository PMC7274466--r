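#include <R.h>
#include <math.h>

/* Right-hand side of the bistable Sup35 aggregation kinetics,
 *
 *   dV/dt = lambda - gamma*V - rho*V*f(S)
 *   dS/dt = rho*V*f(S) - gamma*S,   f(S) = S^n / (K^n + S^n),
 *
 * vectorised over an arbitrary number of cells sharing one parameter set:
 * the state vector is (V_1, S_1, V_2, S_2, ...).  Used through deSolve's
 * compiled-model interface.  The Hill term is evaluated in log space for
 * S > 0 so that large orders n cannot overflow; f(S) = 0 for S <= 0, which
 * makes S = 0 an exactly invariant manifold of the numerical scheme. */

static double parms[5]; /* lambda, gamma, rho, K, n */

void prionide_initmod(void (*odeparms)(int *, double *))
{
    int N = 5;
    odeparms(&N, parms);
}

void prionide_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const double lam = parms[0], gam = parms[1], rho = parms[2];
    const double K = parms[3], n = parms[4];
    const double logK = log(K);
    const int ncell = *neq / 2;

    for (int i = 0; i < ncell; i++) {
        const double V = y[2 * i], S = y[2 * i + 1];
        double f = 0.0;
        if (S > 0.0)
            f = 1.0 / (1.0 + exp(n * (logK - log(S))));
        const double repl = rho * V * f;
        ydot[2 * i] = lam - gam * V - repl;
        ydot[2 * i + 1] = repl - gam * S;
    }
}
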