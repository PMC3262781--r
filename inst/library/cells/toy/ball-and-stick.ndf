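#!ndf
# Toy excitable cell: cylindrical soma with squid Na/K channels and a
# short passive two-segment dendrite.
CELL /toy
  SEGMENT soma
    PARAMETER Vm_init -0.068
    PARAMETER RM 1
    PARAMETER RA 2.5
    PARAMETER CM 0.0164
    PARAMETER ELEAK -0.08
    PARAMETER DIA 2e-05
    PARAMETER LENGTH 4.47e-05
    CHILD channels/hodgkin-huxley.ndf::/na
    CHILD channels/hodgkin-huxley.ndf::/k
    SEGMENT d1
      PARAMETER Vm_init -0.068
      PARAMETER RM 1
      PARAMETER RA 2.5
      PARAMETER CM 0.0164
      PARAMETER ELEAK -0.08
      PARAMETER DIA 1e-05
      PARAMETER LENGTH 5e-05
      SEGMENT d2
        PARAMETER Vm_init -0.068
        PARAMETER RM 1
        PARAMETER RA 2.5
        PARAMETER CM 0.0164
        PARAMETER ELEAK -0.08
        PARAMETER DIA 8e-06
        PARAMETER LENGTH 5e-05
      END
    END
  END
END
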