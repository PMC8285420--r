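target,template_id,phi_refs,retained_pool,assembly
"(0010,0010)",patient_name,patient_name,,phi_first
"(0010,0020)",patient_id,patient_id,,phi_first
"(0010,0030)",birth_date,birth_date,,phi_first
"(0008,0050)",accession,accession_number,,phi_first
"(0008,0090)",referring,referring_physician,,phi_first
"(0008,1050)",performing,performing_physician,,phi_first
"(0008,0080)",institution,institution,,phi_first
"(0008,1030)",study_description,display_name,XR CHEST AP PORTABLE|CT ABDOMEN PELVIS W CONTRAST|MRI KIDNEY W WO CONTRAST,phi_first
"(0010,4000)",patient_comments,aux:name_comma|phone|address,Prep instructions reviewed with patient,phi_first
"(0010,21B0)",patient_history,aux:name_caps,History of hypertension,phi_first
"(0032,4000)",study_comments,aux:operator_name,Routine follow up examination,phi_first
"(0032,1030)",reason_for_study,aux:order_note,Persistent cough,retained_first
"(0032,1060)",requested_procedure,aux:department,CT UROGRAM,retained_first
"(0008,1010)",station_name,aux:station_token,,phi_first
"(0018,1000)",device_serial,aux:serial_no,,phi_first
"(0018,1401)",acq_device_code,aux:img_token,,phi_first
"(0018,0010)",contrast_agent,aux:name_short,ISOVUE-300,retained_first
"(0032,1000)",scheduled_start,aux:sched_date,,phi_first
"(0008,1080)",admitting_diag,aux:admit_token,Chest pain syndrome,retained_first
"(0008,0041)",dataset_subtype,aux:subtype_token,,phi_first
"(0010,0021)",issuer_of_pid,aux:institution_caps,,phi_first
"(0018,1250)",receive_coil,aux:recv_token,,phi_first
"(0018,7006)",detector_desc,aux:detector_token,Flat panel detector,retained_first
"(0008,2111)",derivation_desc,aux:deriv_token,Lossless compression applied,retained_first
"(0032,1070)",requested_contrast,aux:req_token,OMNIPAQUE 350,retained_first
"(3006,0006)",structure_set_desc,aux:struct_token,Pelvis structure set,retained_first
"(3006,0008)",structure_set_date,aux:struct_date,,phi_first
"(0027,""GEMS_IMAG_01"",33)",priv_imaging_options,aux:imaging_token,,phi_first
"(3f01,""INTELERAD MEDICAL SYSTEMS"",03)",priv_source_ae,aux:ae_token,,phi_first
"(7005,""TOSHIBA_MEC_CT3"",1c)",priv_contrast_record,aux:toshiba_token,Contrast agent record,retained_first
"(0009,""GEMS_PETD_01"",37)",priv_batch_desc,aux:batch_token,Batch upload,retained_first
"(0045,""GEMS_SENO_02"",26)",priv_mao_buffer,aux:mao_token,,phi_first
"(0009,""FDMS 1.0"",92)",priv_kanji_dept,aux:kanji_token,,phi_first
"(0009,""GEMS_IDEN_01"",30)",priv_service_id,aux:svc_token,,phi_first
"(0043,""GEMS_PARM_01"",80)",priv_coil_id,aux:coil_token,,phi_first
"(0021,""SIEMENS MR SDS 01"",19)",priv_phoenix,aux:phoenix_token,ASCCONV BEGIN,retained_first
"(0023,""GEMS_STDY_01"",70)",priv_start_time,aux:start_token,,phi_first
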