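// Self-contained xoshiro256++ generator with inverse-transform draws.
// std::random distributions are implementation-defined, so all stochastic
// draws in compiled code go through this header to keep runs reproducible
// for a given seed across toolchains.
#ifndef BASELINEABC_RNG_H
#define BASELINEABC_RNG_H

#include <cstdint>
#include <cmath>

class Xoshiro {
public:
    explicit Xoshiro(uint64_t seed) {
        // splitmix64 expansion of the seed into the 256-bit state
        uint64_t x = seed;
        for (int i = 0; i < 4; ++i) {
            x += 0x9e3779b97f4a7c15ULL;
            uint64_t z = x;
            z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
            z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
            s_[i] = z ^ (z >> 31);
        }
        if (s_[0] == 0 && s_[1] == 0 && s_[2] == 0 && s_[3] == 0)
            s_[0] = 0x9e3779b97f4a7c15ULL;
    }

    inline uint64_t next() {
        const uint64_t result = rotl(s_[0] + s_[3], 23) + s_[0];
        const uint64_t t = s_[1] << 17;
        s_[2] ^= s_[0];
        s_[3] ^= s_[1];
        s_[1] ^= s_[2];
        s_[0] ^= s_[3];
        s_[2] ^= t;
        s_[3] = rotl(s_[3], 45);
        return result;
    }

    // uniform on [0, 1)
    inline double unif() { return (next() >> 11) * 0x1.0p-53; }

    // uniform on (0, 1)
    inline double unif_pos() {
        double u;
        do { u = unif(); } while (u <= 0.0);
        return u;
    }

    inline double rexp(double rate) { return -std::log(unif_pos()) / rate; }

    // unbiased integer on [0, n)
    inline int rint(int n) {
        if (n <= 1) return 0;
        const uint64_t un = static_cast<uint64_t>(n);
        const uint64_t lim = UINT64_MAX - (UINT64_MAX % un);
        uint64_t v;
        do { v = next(); } while (v >= lim);
        return static_cast<int>(v % un);
    }

    inline int rpois(double lambda) {
        if (lambda <= 0.0) return 0;
        int total = 0;
        // additivity: split large means into chunks where Knuth's product
        // method is numerically safe
        while (lambda > 30.0) {
            total += knuth(30.0);
            lambda -= 30.0;
        }
        return total + knuth(lambda);
    }

private:
    inline int knuth(double lambda) {
        const double limit = std::exp(-lambda);
        int k = 0;
        double p = 1.0;
        do {
            ++k;
            p *= unif_pos();
        } while (p > limit);
        return k - 1;
    }

    static inline uint64_t rotl(uint64_t x, int k) {
        return (x << k) | (x >> (64 - k));
    }

    uint64_t s_[4];
};

#endif
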