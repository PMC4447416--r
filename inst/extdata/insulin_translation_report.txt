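Translation report
==================
72 term(s) translated to influences.

rate -> weight mapping (all weights are free parameters):
  k1g        IR <- IRp (+), weight 0.50
  k1r        IR <- IRi (+), weight 0.50
  k1a        IR <- IR*insulin (-), weight 0.50
  k1basal    IR <- IR (-), weight 0.50
  k1basal    IRp <- IR (+), weight 0.50
  k1c        IRp <- IRins (+), weight 0.50
  k1d        IRp <- IRp (-), weight 0.50
  k1g        IRp <- IRp (-), weight 0.50
  k1a        IRins <- IR*insulin (+), weight 0.50
  k1c        IRins <- IRins (-), weight 0.50
  k1d        IRip <- IRp (+), weight 0.50
  k1f        IRip <- IRip*Xp (-), weight 0.50
  k1f        IRi <- IRip*Xp (+), weight 0.50
  k1r        IRi <- IRi (-), weight 0.50
  k2b        IRS1 <- IRS1p (+), weight 0.50
  k2g        IRS1 <- IRS1307 (+), weight 0.50
  k2a        IRS1 <- IRS1*IRip (-), weight 0.50
  k2basal    IRS1 <- IRS1 (-), weight 0.50
  k2a        IRS1p <- IRS1*IRip (+), weight 0.50
  k2d        IRS1p <- IRS1p307 (+), weight 0.50
  k2b        IRS1p <- IRS1p (-), weight 0.50
  k2c        IRS1p <- IRS1p*mTORC1a*diabetes (-), weight 0.50
  k2c        IRS1p307 <- IRS1p*mTORC1a*diabetes (+), weight 0.50
  k2d        IRS1p307 <- IRS1p307 (-), weight 0.50
  k2f        IRS1p307 <- IRS1p307 (-), weight 0.50
  k2f        IRS1307 <- IRS1p307 (+), weight 0.50
  k2basal    IRS1307 <- IRS1 (+), weight 0.50
  k2g        IRS1307 <- IRS1307 (-), weight 0.50
  k3b        X <- Xp (+), weight 0.50
  k3a        X <- X*IRS1p (-), weight 0.50
  k3a        Xp <- X*IRS1p (+), weight 0.50
  k3b        Xp <- Xp (-), weight 0.50
  k4b        PKB <- PKB308p (+), weight 0.50
  k4h        PKB <- PKB473p (+), weight 0.50
  k4a        PKB <- PKB*IRS1p (-), weight 0.50
  k4a        PKB308p <- PKB*IRS1p (+), weight 0.50
  k4b        PKB308p <- PKB308p (-), weight 0.50
  k4c        PKB308p <- PKB308p*mTORC2a (-), weight 0.50
  k4f        PKB473p <- PKB308p473p (+), weight 0.50
  k4e        PKB473p <- PKB473p*IRS1p307 (-), weight 0.50
  k4h        PKB473p <- PKB473p (-), weight 0.50
  k4c        PKB308p473p <- PKB308p*mTORC2a (+), weight 0.50
  k4e        PKB308p473p <- PKB473p*IRS1p307 (+), weight 0.50
  k4f        PKB308p473p <- PKB308p473p (-), weight 0.50
  k5b        mTORC1 <- mTORC1a (+), weight 0.50
  k5a1       mTORC1 <- mTORC1*PKB308p473p (-), weight 0.50
  k5a2       mTORC1 <- mTORC1*PKB308p (-), weight 0.50
  k5a1       mTORC1a <- mTORC1*PKB308p473p (+), weight 0.50
  k5a2       mTORC1a <- mTORC1*PKB308p (+), weight 0.50
  k5b        mTORC1a <- mTORC1a (-), weight 0.50
  k5d        mTORC2 <- mTORC2a (+), weight 0.50
  k5c        mTORC2 <- mTORC2*IRip (-), weight 0.50
  k5c        mTORC2a <- mTORC2*IRip (+), weight 0.50
  k5d        mTORC2a <- mTORC2a (-), weight 0.50
  k6b        AS160 <- AS160p (+), weight 0.50
  k6f1       AS160 <- AS160*PKB308p473p (-), weight 0.50
  k6f2       AS160 <- AS160*PKB473p (-), weight 0.50
  k6f1       AS160p <- AS160*PKB308p473p (+), weight 0.50
  k6f2       AS160p <- AS160*PKB473p (+), weight 0.50
  k6b        AS160p <- AS160p (-), weight 0.50
  k7f        GLUT4m <- GLUT4*AS160p (+), weight 0.50
  k7b        GLUT4m <- GLUT4m (-), weight 0.50
  k7b        GLUT4 <- GLUT4m (+), weight 0.50
  k7f        GLUT4 <- GLUT4*AS160p (-), weight 0.50
  k9b1       S6K <- S6Kp (+), weight 0.50
  k9f1       S6K <- S6K*mTORC1a (-), weight 0.50
  k9f1       S6Kp <- S6K*mTORC1a (+), weight 0.50
  k9b1       S6Kp <- S6Kp (-), weight 0.50
  k9b2       S6 <- S6p (+), weight 0.50
  k9f2       S6 <- S6*S6Kp (-), weight 0.50
  k9f2       S6p <- S6*S6Kp (+), weight 0.50
  k9b2       S6p <- S6p (-), weight 0.50

4 saturation denominator(s) dropped:
  AS160 (rate k6f2): PKB473p^n6 / (km6^n6 + PKB473p^n6) -> PKB473p
  AS160p (rate k6f2): PKB473p^n6 / (km6^n6 + PKB473p^n6) -> PKB473p
  S6K (rate k9f1): mTORC1a^n9 / (km9^n9 + mTORC1a^n9) -> mTORC1a
  S6Kp (rate k9f1): mTORC1a^n9 / (km9^n9 + mTORC1a^n9) -> mTORC1a
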